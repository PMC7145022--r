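## Stage 6 — group discrimination.
## Procrustes-distance permutation tests between group mean shapes, CVA
## ordination, and leave-one-out discriminant classification on retained
## PC scores (confusion matrices in row-percent).

source("analysis/00_common.R")
s3 <- readRDS(cache_file("stage3_space.rds"))
s4 <- readRDS(cache_file("stage4_pca.rds"))
space <- s3$space; meta <- s3$meta

k <- 0
for (f in c("ethnicity", "sex")) {
  k <- k + 1
  gs <- unique(meta[[f]])
  pt <- permutation_test_group_distance(space, meta[[f]], groups = gs,
                                        n_perm = cfg$n_perm,
                                        seed = cfg$seed + 100 + k)
  cat(sprintf("Procrustes distance %s (%s vs %s): %.4f, p = %s\n",
              f, gs[1], gs[2], pt$observed, format.pval(pt$p_value)))
}

cat("\nleave-one-out discriminant classification on", s4$keep,
    "retained PCs:\n")
for (f in c("ethnicity", "sex", "age_class")) {
  r <- discriminant_classify(s4$pca$scores, meta[[f]], max_q = s4$keep)
  cat("\n--", f, ": accuracy", round(r$accuracy, 2), "% | Wilks",
      signif(r$wilks, 4), "p", format.pval(r$wilks_p), "\n")
  print(round(r$confusion, 2))
  cm <- as.data.frame.matrix(round(r$confusion, 2))
  utils::write.csv(cbind(true_group = rownames(cm), cm),
                   table_file(paste0("confusion_", f, ".csv")),
                   row.names = FALSE)
}

cv <- cva(s4$pca$scores[, seq_len(s4$keep), drop = FALSE], meta$sex)
utils::write.csv(data.frame(id = space$ids, sex = meta$sex,
                            CV1 = cv$scores[, 1]),
                 table_file("cva_sex_scores.csv"), row.names = FALSE)
cat("\nCVA (sex): between/within eigenvalue on CV1 =",
    round(cv$eigenvalues[1], 3), "\n")
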