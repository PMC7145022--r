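## Stage 4 — relative warps and distance analysis.
## PCA of the tangent-space coordinates with parallel-analysis component
## retention, and EDMA log10 inter-anchor distance tables on the group
## mean shapes (rescaled to mm by the group mean centroid size).

source("analysis/00_common.R")
s1 <- readRDS(cache_file("stage1.rds"))
s3 <- readRDS(cache_file("stage3_space.rds"))
space <- s3$space; meta <- s3$meta

pca <- shape_pca(space)
keep <- parallel_analysis_retention(space, quantile = cfg$pa_quantile,
                                    seed = cfg$seed + 1)
cat("PC1 explains", round(pca$variance_fractions[1], 2), "%; PC2",
    round(pca$variance_fractions[2], 2), "%\n")
cat("parallel analysis retains", keep, "of", pca$retained_count,
    "components\n")
utils::write.csv(
  data.frame(component = seq_along(pca$eigenvalues),
             eigenvalue = pca$eigenvalues,
             variance_pct = pca$variance_fractions,
             retained = seq_along(pca$eigenvalues) <= keep),
  table_file("pca_summary.csv"), row.names = FALSE)

labs <- s1$tmpl$landmarks$labels
edma_table <- function(groups) {
  means <- group_mean_shapes_mm(space, groups)
  out <- data.frame(pair = TABLE_DISTANCE_PAIRS)
  for (g in names(means)) {
    m <- means[[g]][seq_along(labs), , drop = FALSE]
    rownames(m) <- labs
    out[[g]] <- round(edma_log_distances(m,
                                         TABLE_DISTANCE_PAIRS)$log10_distance, 3)
  }
  out
}
sex_tab <- edma_table(meta$sex)
utils::write.csv(sex_tab, table_file("edma_sex.csv"), row.names = FALSE)
cat("\nlog10 anthropometric distances by sex:\n")
print(sex_tab, row.names = FALSE)
age_tab <- edma_table(paste(meta$age_class, meta$sex, sep = "."))
utils::write.csv(age_tab, table_file("edma_age.csv"), row.names = FALSE)

saveRDS(list(pca = pca, keep = keep), cache_file("stage4_pca.rds"))
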