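# Staged pipeline driver: every artifact is reproducible from the resolved
# configuration plus the single seed it records.

.pipeline_stage_order <- c("simulate", "build-networks", "normalize",
                           "factorize", "fuse", "call-strong", "classify",
                           "evaluate")

.pipeline_defaults <- function() {
  list(stages = "all",
       out_dir = "tftensor_run",
       seed = 1L,
       verbose = TRUE,
       simulate = list(n_tfs = 30L,
                       lineages = list(BL = 4L, CA = 4L, EN = 4L),
                       shared_modules = list(1:5),
                       specific_modules = list(BL = list(6:10),
                                               CA = list(11:15),
                                               EN = list(16:20)),
                       edge_noise = 0.05,
                       baseline_occupancy = 0.08,
                       module_target_count = NULL),
       prior = list(R_init = 8L, max_iter = 100L, tol = 1e-6,
                    a0 = 1e-6, b0 = 1e-6, c0 = 1e-6, d0 = 1e-6,
                    prune_threshold = 1e-4),
       normalize = list(lower_pct = 5, upper_pct = 95),
       strong = list(alpha = 1.5, hub_fraction = 0.05),
       evaluate = list(threshold = 0.8))
}

.merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])) && k != "simulate")
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.as_int_modules <- function(x) lapply(x, as.integer)

#' Run the integration pipeline
#'
#' Executes the selected stages in order: `simulate` (lineage-structured
#' regulatory networks), `build-networks` (co-occupancy Jaccard),
#' `normalize`, `factorize` (Bayesian CP per lineage), `fuse` (cell-lineage
#' networks), `call-strong`, `classify`, `evaluate` (ROC/AUC of CL-Nets and
#' AI-Nets against the network-averaging gold standard). `"all"` runs every
#' stage. Later stages read earlier stages' artifacts from `out_dir` when
#' those stages are not part of the current run, and fail before any
#' computation when an input is missing.
#'
#' @param config named list, or path to a YAML file, overriding the
#'   defaults; unknown keys are rejected. Keys: `stages`, `out_dir`,
#'   `seed`, `verbose`, `simulate`, `prior`, `normalize`, `strong`,
#'   `evaluate`.
#' @return invisibly, a list with the in-memory artifacts (`networks`,
#'   `states`, `cl_nets`, `strong`, `classification`, `evaluation`) and the
#'   resolved config.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.pipeline_defaults(), config)
  stages <- cfg$stages
  if ("all" %in% stages) stages <- .pipeline_stage_order
  bad <- setdiff(stages, .pipeline_stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .pipeline_stage_order[.pipeline_stage_order %in% stages]
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out, "resolved_config.yaml"))
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  regnets <- NULL; networks <- NULL; normalized <- NULL
  states <- NULL; cl_nets <- NULL; strong <- NULL
  classification <- NULL; evaluation <- NULL

  lineage_dirs <- function(root) {
    d <- list.dirs(file.path(out, root), recursive = FALSE)
    stats::setNames(d, basename(d))
  }
  load_networks <- function(root) {
    dirs <- lineage_dirs(root)
    if (length(dirs) == 0L) return(NULL)
    lapply(dirs, function(d) {
      fs <- sort(list.files(d, pattern = "\\.tsv$", full.names = TRUE))
      stats::setNames(lapply(fs, read_matrix_tsv),
                      sub("\\.tsv$", "", basename(fs)))
    })
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      "simulate" = {
        sim <- cfg$simulate
        regnets <- gen_regulatory_networks(
          n_tfs = sim$n_tfs,
          lineages = unlist(sim$lineages),
          shared_modules = .as_int_modules(sim$shared_modules),
          specific_modules = lapply(sim$specific_modules, .as_int_modules),
          edge_noise = sim$edge_noise,
          seed = cfg$seed + 101L,
          baseline_occupancy = sim$baseline_occupancy,
          module_target_count = sim$module_target_count)
        for (lin in names(regnets)) {
          d <- file.path(out, "edge_lists", lin)
          dir.create(d, showWarnings = FALSE, recursive = TRUE)
          for (ct in names(regnets[[lin]]))
            write_edge_list(regnets[[lin]][[ct]],
                            file.path(d, paste0(ct, ".tsv")))
        }
      },
      "build-networks" = {
        if (is.null(regnets)) {
          dirs <- lineage_dirs("edge_lists")
          if (length(dirs) == 0L)
            stop("stage 'build-networks' requires regulatory edge lists; ",
                 "run 'simulate' first or place them under ",
                 file.path(out, "edge_lists"))
          tfs <- NULL
          regnets <- lapply(dirs, function(d) {
            fs <- sort(list.files(d, pattern = "\\.tsv$", full.names = TRUE))
            stats::setNames(lapply(fs, read_edge_list, tf_universe = NULL),
                            sub("\\.tsv$", "", basename(fs)))
          })
          # harmonize TF universe across all cell types
          tfs <- sort(unique(unlist(lapply(regnets, function(l)
            lapply(l, function(n) n$tf_universe)))))
          regnets <- lapply(regnets, function(l)
            lapply(l, function(n) regulatory_network(n$edges, tfs)))
        }
        networks <- lapply(regnets, function(l) lapply(l, cooccupancy_jaccard))
        for (lin in names(networks)) {
          d <- file.path(out, "ct_networks", lin)
          dir.create(d, showWarnings = FALSE, recursive = TRUE)
          for (ct in names(networks[[lin]]))
            write_matrix_tsv(networks[[lin]][[ct]],
                             file.path(d, paste0(ct, ".tsv")))
        }
      },
      "normalize" = {
        if (is.null(networks)) networks <- load_networks("ct_networks")
        if (is.null(networks))
          stop("stage 'normalize' requires cell-type networks; run ",
               "'build-networks' first")
        normalized <- lapply(networks, function(l)
          lapply(l, normalize_network,
                 lower_pct = cfg$normalize$lower_pct,
                 upper_pct = cfg$normalize$upper_pct))
        for (lin in names(normalized)) {
          d <- file.path(out, "ct_networks_normalized", lin)
          dir.create(d, showWarnings = FALSE, recursive = TRUE)
          for (ct in names(normalized[[lin]]))
            write_matrix_tsv(normalized[[lin]][[ct]],
                             file.path(d, paste0(ct, ".tsv")))
        }
      },
      "factorize" = {
        if (is.null(normalized)) normalized <- load_networks("ct_networks_normalized")
        if (is.null(normalized))
          stop("stage 'factorize' requires normalized networks; run ",
               "'normalize' first")
        pc <- cfg$prior
        states <- list()
        for (lin in names(normalized)) {
          tens <- stack_tensor(normalized[[lin]])
          conf <- cp_prior_config(a0 = pc$a0, b0 = pc$b0, c0 = pc$c0,
                                  d0 = pc$d0, R_init = pc$R_init,
                                  max_iter = pc$max_iter, tol = pc$tol,
                                  prune_threshold = pc$prune_threshold,
                                  seed = cfg$seed + 211L)
          states[[lin]] <- suppressWarnings(bcpf(tens, conf))
          say("  factorize[%s]: rank %d after %d sweeps", lin,
              states[[lin]]$rank, length(states[[lin]]$elbo_trace))
        }
      },
      "fuse" = {
        if (is.null(states))
          stop("stage 'fuse' requires factorization states; run 'factorize' ",
               "in the same invocation")
        cl_nets <- lapply(states, fuse_network_mode)
        dir.create(file.path(out, "cl_networks"), showWarnings = FALSE,
                   recursive = TRUE)
        for (lin in names(cl_nets))
          write_matrix_tsv(cl_nets[[lin]],
                           file.path(out, "cl_networks", paste0(lin, ".tsv")))
      },
      "call-strong" = {
        if (is.null(cl_nets))
          stop("stage 'call-strong' requires fused lineage networks; run ",
               "'fuse' first")
        sc <- strong_edge_config(alpha = cfg$strong$alpha,
                                 hub_fraction = cfg$strong$hub_fraction)
        strong <- lapply(cl_nets, strong_interactions, config = sc)
        dir.create(file.path(out, "strong_edges"), showWarnings = FALSE,
                   recursive = TRUE)
        for (lin in names(strong))
          utils::write.table(strong[[lin]],
                             file.path(out, "strong_edges",
                                       paste0(lin, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "classify" = {
        if (is.null(strong))
          stop("stage 'classify' requires strong-edge calls; run ",
               "'call-strong' first")
        classification <- classify_edges(strong)
        utils::write.table(classification$edges,
                           file.path(out, "classification.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(classification$summary,
                           file.path(out, "classification_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        prof <- degree_profile(strong, cl_nets[[1]]$nodes)
        utils::write.table(prof, file.path(out, "degree_profile.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA)
      },
      "evaluate" = {
        if (is.null(cl_nets))
          stop("stage 'evaluate' requires fused lineage networks; run ",
               "'fuse' first")
        if (is.null(normalized)) normalized <- load_networks("ct_networks_normalized")
        if (is.null(normalized))
          stop("stage 'evaluate' requires normalized cell-type networks")
        gold <- build_gold_standard_avg(unlist(normalized, recursive = FALSE),
                                        threshold = cfg$evaluate$threshold)
        labels <- binarize_gold(gold)
        dir.create(file.path(out, "evaluation"), showWarnings = FALSE,
                   recursive = TRUE)
        evaluation <- list()
        for (lin in names(cl_nets)) {
          idx <- cbind(match(labels$tf_a, cl_nets[[lin]]$nodes),
                       match(labels$tf_b, cl_nets[[lin]]$nodes))
          cl_scores <- cl_nets[[lin]]$weights[idx]
          ai <- ai_net(normalized[[lin]])
          ai_scores <- ai$weights[idx]
          ok <- !is.na(cl_scores) & !is.na(ai_scores)
          res_cl <- roc_auc(cl_scores[ok], labels$label[ok])
          res_ai <- roc_auc(ai_scores[ok], labels$label[ok])
          utils::write.table(res_cl$roc,
                             file.path(out, "evaluation",
                                       paste0(lin, "_roc.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          evaluation[[lin]] <- list(auc_cl = res_cl$auc, auc_ai = res_ai$auc,
                                    n_pairs = sum(ok))
          say("  evaluate[%s]: CL-Net AUC %.3f, AI-Net AUC %.3f", lin,
              res_cl$auc, res_ai$auc)
        }
        jsonlite::write_json(evaluation,
                             file.path(out, "evaluation", "auc_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      })
    say("stage %-14s done in %.1fs", stage,
        proc.time()[["elapsed"]] - t0)
  }
  invisible(list(config = cfg, networks = networks, normalized = normalized,
                 states = states, cl_nets = cl_nets, strong = strong,
                 classification = classification, evaluation = evaluation))
}
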