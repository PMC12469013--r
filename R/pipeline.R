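#' Write a score map as a two-column TSV
#'
#' Rows sorted by descending score, ties by smaller label — the package's
#' standard `node score` contract.
#' @param scores named numeric score map.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_scores <- function(scores, file) {
  ord <- order(-scores, label_rank(names(scores)))
  df <- data.frame(node = names(scores)[ord], score = unname(scores[ord]))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Run the full identification and evaluation pipeline
#'
#' Reads a network, keeps its largest component, writes every centrality
#' score map, the SNEFLD-SM ranking, the SI infection curve seeded at the
#' top-k ranked nodes, the Kendall-tau-vs-infectivity profile over a beta
#' grid, the top-k Jaccard overlap with the standard centralities, the
#' robustness curve under ranked removal, and a JSON manifest (configuration
#' plus input checksum) for reproducibility.
#'
#' @param input path to an edge-list or GML network file.
#' @param out_dir output directory (created if missing).
#' @param lambda,orientation passed to [snefld_sm()].
#' @param beta infection probability for the seeded SI curve (default 0.1).
#' @param beta_grid beta values for the tau profile (default 0.01..0.1);
#'   `NULL` skips the (costly) infectivity stage.
#' @param t_max SI curve length; `t_obs` infectivity observation step;
#'   `runs` replicates; `top_k` seed-set / overlap size; `rng_seed` RNG seed.
#' @param format input format, see [read_network()].
#' @return invisibly, a list with the ranking and the manifest.
#' @export
run_pipeline <- function(input, out_dir, lambda = 0.5,
                         orientation = "magnitude", beta = 0.1,
                         beta_grid = seq(0.01, 0.1, by = 0.01), t_max = 30,
                         t_obs = 10, runs = 100, top_k = 10, rng_seed = 1,
                         format = "auto") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g0 <- read_network(input, format = format)
  g <- largest_component(g0)
  message(sprintf("input: %d nodes / %d edges; largest component: %d / %d",
                  gorder(g0), gsize(g0), gorder(g), gsize(g)))
  utils::write.table(network_summary(g), file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dm <- all_pairs_distances(g)
  scores <- list(
    dc = degree_centrality(g), csn = second_order_centrality(g),
    bc = betweenness_centrality(g), cc = closeness_centrality(g, dm),
    le = local_entropy(g), me = mapping_entropy(g), snb = snb_entropy(g),
    ld = suppressWarnings(local_dimension(g, dm)),
    fld = suppressWarnings(fuzzy_local_dimension(g, dm))
  )
  for (m in names(scores)) {
    write_scores(scores[[m]], file.path(out_dir, paste0("scores_", m, ".tsv")))
  }

  ranked <- snefld_sm(g, lambda = lambda, orientation = orientation)
  utils::write.table(ranked, file.path(out_dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf("top node: %s", ranked$node[1]))

  kk <- min(top_k, gorder(g))
  curve <- si_simulate(g, beta = beta, seeds = ranked$node[seq_len(kk)],
                       t_max = t_max, runs = runs, rng_seed = rng_seed)
  utils::write.table(curve, file.path(out_dir, "si_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  jc <- vapply(c("dc", "bc", "cc", "fld"), function(m) {
    jaccard_topk(ranked, scores[[m]], k = kk)
  }, numeric(1))
  utils::write.table(data.frame(measure = names(jc), jaccard = unname(jc)),
                     file.path(out_dir, "jaccard.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  rob <- robustness_curve(g, ranked, fractions = seq(0, 1, by = 0.01))
  utils::write.table(rob, file.path(out_dir, "robustness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tau_profile <- NULL
  if (!is.null(beta_grid)) {
    snefld_scores <- stats::setNames(ranked$score, ranked$node)
    tau_profile <- data.frame(beta = beta_grid, tau = NA_real_)
    for (i in seq_along(beta_grid)) {
      infect <- node_infectivity(g, beta = beta_grid[i], t_obs = t_obs,
                                 runs = runs, rng_seed = rng_seed)
      tau_profile$tau[i] <- kendall_tau(snefld_scores, infect)$tau
    }
    utils::write.table(tau_profile, file.path(out_dir, "tau_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    input = normalizePath(input), input_md5 = unname(tools::md5sum(input)),
    n_nodes = gorder(g), n_edges = gsize(g),
    lambda = lambda, orientation = orientation, beta = beta,
    beta_grid = beta_grid, t_max = t_max, t_obs = t_obs, runs = runs,
    top_k = top_k, rng_seed = rng_seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(ranking = ranked, manifest = manifest,
                 tau_profile = tau_profile))
}

#' Rebuild the comparison tables for user-supplied datasets
#'
#' For each named dataset path, computes the topology summary row and the
#' top-k node table of SNEFLD-SM next to the standard comparators (DC, BC,
#' CC, FLD), with the Jaccard overlap of each comparator's top-k set against
#' SNEFLD-SM's. Nothing is downloaded: callers supply local edge-list or GML
#' files.
#'
#' @param paths named character vector or list of dataset file paths.
#' @param top_k table depth (default 10).
#' @param lambda,orientation passed to [snefld_sm()].
#' @return a list per dataset, each with elements `summary` (one-row
#'   data.frame), `top` (top_k x methods character data.frame) and `jaccard`
#'   (named numeric vector vs SNEFLD-SM).
#' @export
reproduce_tables <- function(paths, top_k = 10, lambda = 0.5,
                             orientation = "magnitude") {
  out <- list()
  for (nm in names(paths)) {
    g <- largest_component(read_network(paths[[nm]]))
    dm <- all_pairs_distances(g)
    ranked <- snefld_sm(g, lambda = lambda, orientation = orientation)
    comps <- list(
      dc = degree_centrality(g), bc = betweenness_centrality(g),
      cc = closeness_centrality(g, dm),
      fld = suppressWarnings(fuzzy_local_dimension(g, dm))
    )
    kk <- min(top_k, gorder(g))
    top <- data.frame(rank = seq_len(kk), snefld_sm = ranked$node[seq_len(kk)],
                      stringsAsFactors = FALSE)
    for (m in names(comps)) top[[m]] <- rank_nodes(comps[[m]])[seq_len(kk)]
    jc <- vapply(comps, function(s) jaccard_topk(ranked, s, k = kk), numeric(1))
    out[[nm]] <- list(summary = cbind(data.frame(network = nm),
                                      network_summary(g)),
                      top = top, jaccard = jc)
  }
  out
}
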