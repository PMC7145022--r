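## Stage 3 — superimposition and error assessment.
## Generalized Procrustes analysis of the homologous configurations, then
## the hierarchical Procrustes ANOVA (ethnicity, sex, age, individual,
## digitizing error) over the three landmark partitions: fixed anchors,
## sliding semi-landmarks, and all 500.

source("analysis/00_common.R")
s1 <- readRDS(cache_file("stage1.rds"))
slid <- readRDS(cache_file("stage2_slid.rds"))
meta <- s1$pop$meta

configs <- aperm(simplify2array(lapply(slid, function(s)
  s$landmarks$points)), c(3, 1, 2))

tabs <- do.call(rbind, lapply(c("anchors", "semilandmarks", "all"),
                              function(p) {
  tab <- procrustes_anova(configs, meta, partition = p, anchor_count = 20)
  cbind(partition = p, as.data.frame(tab))
}))
utils::write.csv(tabs, table_file("procrustes_anova.csv"),
                 row.names = FALSE)
print(tabs, digits = 3, row.names = FALSE)

## shape space of the first digitizations, for all downstream statistics
firsts <- is.na(meta$replicate_of)
space <- gpa(configs[firsts, , , drop = FALSE], ids = meta$id[firsts])
cat("\nGPA converged in", space$iterations, "iterations;",
    sum(firsts), "specimens x", dim(space$aligned)[2], "landmarks\n")
saveRDS(list(space = space, meta = meta[firsts, ]),
        cache_file("stage3_space.rds"))
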