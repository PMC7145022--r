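#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with its default: 480
#' surface semi-landmarks at a 1.5 mm spacing radius, six sliding cycles
#' with the step fraction decaying from 1.00 to 0.05, 10,000 permutations
#' for the significance tests, a 0.95 parallel-analysis quantile, and a
#' 99.98% variance cutoff for the MANOVA feature space. Configurations
#' round-trip through YAML.
#'
#' @param n_semilandmarks,radius template options.
#' @param cycles,step_start,step_end,beta sliding/TPS options.
#' @param n_perm,pa_quantile,manova_cutoff statistics options.
#' @param population a [population_spec()] for synthetic runs.
#' @param seed master seed; all pipeline randomness derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_semilandmarks = 480, radius = 1.5,
                            cycles = 6, step_start = 1.00, step_end = 0.05,
                            beta = 0, n_perm = 10000, pa_quantile = 0.95,
                            manova_cutoff = 0.9998,
                            population = population_spec(), seed = 1) {
  structure(list(n_semilandmarks = n_semilandmarks, radius = radius,
                 cycles = cycles, step_start = step_start,
                 step_end = step_end, beta = beta, n_perm = n_perm,
                 pa_quantile = pa_quantile, manova_cutoff = manova_cutoff,
                 population = population, seed = seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pop <- raw$population
  pop$counts <- if (is.list(pop$counts) || length(pop$counts) == 20)
    array(unlist(pop$counts), c(2, 2, 5)) else pop$counts %||% "default"
  raw$population <- do.call(population_spec, c(
    list(n_per_cell = pop$counts),
    pop[setdiff(names(pop), c("counts", "head_params"))],
    list(head_params = do.call(make_head_params, pop$head_params))))
  do.call(pipeline_config, raw[setdiff(names(raw), "population")] |>
            c(list(population = raw$population)))
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  pop <- unclass(cfg$population)
  pop$counts <- as.numeric(pop$counts)
  pop$head_params <- unclass(pop$head_params)
  cfg$population <- pop
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> template -> warp/slide -> GPA -> statistics ->
#' classification on a synthetic population and writes every report table
#' to `out_dir`: sliding traces, the aligned shape archive, Procrustes
#' ANOVA over the three landmark partitions (anchors, semi-landmarks,
#' all), a PCA summary with parallel-analysis retention, EDMA distance
#' tables by sex and by age class, per-group allometry regressions, the
#' MANOVA slope/intercept tests, group Procrustes-distance permutation
#' tests and cross-validated confusion matrices per factor. `run_info.json`
#' records the configuration, its hash, the seed and per-stage timings,
#' so a re-run with the same configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results.
#' @export
run_full_analysis <- function(config = pipeline_config(),
                              out_dir = "results") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[", name, "] ...")
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  ## --- simulate -------------------------------------------------------
  tmpl <- stage("template", {
    base <- make_head_mesh(config$population$head_params)
    generate_template_semilandmarks(base$mesh, base$anchors,
                                    n = config$n_semilandmarks,
                                    radius = config$radius,
                                    seed = config$seed)
  })
  pop <- stage("simulate", sample_population(config$population,
                                             template = tmpl))
  meta <- pop$meta

  ## --- warp + slide ---------------------------------------------------
  slid <- stage("warp", {
    out <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      ind <- if (is.na(meta$replicate_of[i])) meta$id[i] else
        meta$replicate_of[i]
      tr <- slide_semilandmarks(tmpl, pop$meshes[[ind]],
                                pop$anchors[[meta$id[i]]],
                                cycles = config$cycles,
                                step_start = config$step_start,
                                step_end = config$step_end)
      out[[i]] <- tr
    }
    names(out) <- meta$id
    out
  })
  traces <- data.frame(id = meta$id,
                       E_i = vapply(slid, function(s) s$initial_energy, 0),
                       E_f = vapply(slid, function(s)
                         s$energies[length(s$energies)], 0))
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            step_fractions = slid[[1]]$step_fractions,
                            energies = lapply(slid, `[[`, "energies")),
                       file.path(out_dir, "sliding_traces.json"),
                       auto_unbox = TRUE, digits = NA)

  ## --- GPA + shape archive -------------------------------------------
  space <- stage("gpa", {
    arr <- as_config_array(lapply(slid, function(s) s$landmarks))
    gpa(arr, ids = meta$id)
  })
  K <- dim(space$aligned)[2]
  flat <- data.frame(id = rep(meta$id, each = K),
                     landmark = rep(rownames(tmpl$landmarks$points),
                                    times = nrow(meta)),
                     matrix(aperm(space$aligned, c(2, 1, 3)),
                            ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  .write_table(flat, file.path(out_dir, "shapes_aligned.csv"))
  .write_table(data.frame(id = meta$id,
                          centroid_size = space$centroid_sizes),
               file.path(out_dir, "centroid_sizes.csv"))
  write_metadata(meta, file.path(out_dir, "metadata.csv"))

  ## --- Procrustes ANOVA, three partitions ----------------------------
  anova_tabs <- stage("procrustes_anova", {
    arr <- as_config_array(lapply(slid, function(s) s$landmarks))
    parts <- c("anchors", "semilandmarks", "all")
    do.call(rbind, lapply(parts, function(p) {
      tab <- procrustes_anova(arr, meta, partition = p,
                              anchor_count = tmpl$landmarks$anchor_count)
      cbind(partition = p, as.data.frame(tab))
    }))
  })
  .write_table(anova_tabs, file.path(out_dir, "procrustes_anova.csv"))

  ## --- PCA ------------------------------------------------------------
  firsts <- is.na(meta$replicate_of)
  space1 <- gpa(space$aligned[firsts, , , drop = FALSE] *
                  rep(space$centroid_sizes[firsts],
                      times = K * 3),
                ids = meta$id[firsts])
  pca_res <- stage("pca", shape_pca(space1))
  retained <- stage("parallel_analysis",
                    parallel_analysis_retention(space1,
                                                quantile = config$pa_quantile,
                                                seed = config$seed + 1))
  .write_table(data.frame(component = seq_along(pca_res$eigenvalues),
                          eigenvalue = pca_res$eigenvalues,
                          variance_pct = pca_res$variance_fractions,
                          retained = seq_along(pca_res$eigenvalues) <=
                            retained),
               file.path(out_dir, "pca_summary.csv"))

  meta1 <- meta[firsts, ]
  ## --- EDMA -----------------------------------------------------------
  edma <- stage("edma", {
    labs <- tmpl$landmarks$labels
    by_sex <- group_mean_shapes_mm(space1, meta1$sex)
    sex_tab <- data.frame(pair = TABLE_DISTANCE_PAIRS)
    for (g in names(by_sex)) {
      cfgm <- by_sex[[g]][seq_along(labs), , drop = FALSE]
      rownames(cfgm) <- labs
      sex_tab[[g]] <- edma_log_distances(cfgm,
                                         TABLE_DISTANCE_PAIRS)$log10_distance
    }
    age_tab <- data.frame(pair = TABLE_DISTANCE_PAIRS)
    for (a in AGE_CLASSES) for (s in c("male", "female")) {
      sel <- meta1$age_class == a & meta1$sex == s
      if (sum(sel) < 2) next
      sub <- gpa(space1$aligned[sel, , , drop = FALSE],
                 ids = meta1$id[sel])
      m <- apply(space1$aligned[sel, , , drop = FALSE], c(2, 3), mean) *
        mean(space1$centroid_sizes[sel])
      rownames(m)[seq_along(labs)] <- labs
      age_tab[[paste(a, s, sep = ".")]] <-
        edma_log_distances(m[seq_along(labs), ],
                           TABLE_DISTANCE_PAIRS)$log10_distance
    }
    list(sex = sex_tab, age = age_tab)
  })
  .write_table(edma$sex, file.path(out_dir, "edma_sex.csv"))
  .write_table(edma$age, file.path(out_dir, "edma_age.csv"))

  ## --- allometry ------------------------------------------------------
  allom <- stage("allometry", {
    rows <- list()
    grp_defs <- list(ethnicity = meta1$ethnicity, sex = meta1$sex,
                     age_class = meta1$age_class)
    sd_idx <- 0
    for (f in names(grp_defs)) {
      for (g in unique(grp_defs[[f]])) {
        sel <- grp_defs[[f]] == g
        if (sum(sel) < 5) next
        sd_idx <- sd_idx + 1
        r <- regress_shape_on_size(space1, subset = sel,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 10 + sd_idx)
        rows[[length(rows) + 1]] <-
          data.frame(factor = f, group = g, n = sum(sel),
                     percent_predicted = r$percent_predicted,
                     p_value = r$p_value)
      }
    }
    do.call(rbind, rows)
  })
  .write_table(allom, file.path(out_dir, "allometry.csv"))

  ## --- MANOVA ---------------------------------------------------------
  manova_tab <- stage("manova", {
    rows <- list()
    vf <- cumsum(pca_res$variance_fractions) / 100
    for (f in c("ethnicity", "sex", "age_class")) {
      g <- length(unique(meta1[[f]]))
      q_cut <- max(1L, which(vf >= config$manova_cutoff)[1])
      q_max <- sum(firsts) - 2L * g - 2L
      if (q_cut > q_max)
        message("manova: shrinking feature count from ", q_cut, " to ",
                q_max, " (residual degrees of freedom)")
      m <- manova_allometry(pca_res, meta1[[f]], space1$centroid_sizes,
                            q = min(q_cut, q_max))
      rows[[f]] <- cbind(factor = f, as.data.frame(m))
    }
    do.call(rbind, rows)
  })
  .write_table(manova_tab, file.path(out_dir, "manova.csv"))

  ## --- distances + classification -------------------------------------
  dist_tab <- stage("permutation_distances", {
    rows <- list()
    pd_idx <- 0
    for (f in c("ethnicity", "sex")) {
      gs <- unique(meta1[[f]])
      pd_idx <- pd_idx + 1
      pt <- permutation_test_group_distance(space1, meta1[[f]],
                                            groups = gs,
                                            n_perm = config$n_perm,
                                            seed = config$seed + 100 + pd_idx)
      rows[[f]] <- data.frame(factor = f,
                              group_1 = gs[1], group_2 = gs[2],
                              distance = pt$observed, p = pt$p_value)
    }
    do.call(rbind, rows)
  })
  .write_table(dist_tab, file.path(out_dir, "procrustes_distances.csv"))

  cls <- stage("classify", {
    out <- list()
    for (f in c("ethnicity", "sex", "age_class")) {
      cr <- discriminant_classify(pca_res$scores, meta1[[f]],
                                  max_q = retained)
      cm <- as.data.frame.matrix(round(cr$confusion, 2))
      cm <- cbind(true_group = rownames(cm), cm,
                  accuracy = round(cr$per_group_accuracy, 2))
      .write_table(cm, file.path(out_dir, paste0("confusion_", f, ".csv")))
      out[[f]] <- cr
    }
    out
  })

  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         n_specimens = sum(firsts), n_records = nrow(meta),
         n_landmarks = K, pca_retained = retained,
         accuracy = lapply(cls, function(c) c$accuracy),
         timings = timings),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  message("run_full_analysis: wrote ", length(list.files(out_dir)),
          " artifacts to ", out_dir)
  invisible(list(template = tmpl, population = pop, traces = slid,
                 shape_space = space, shape_space_firsts = space1,
                 anova = anova_tabs, pca = pca_res, retained = retained,
                 edma = edma, allometry = allom, manova = manova_tab,
                 distances = dist_tab, classification = cls))
}
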