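# Scoring detected partitions: normalized mutual information, pairwise
# information-retrieval metrics, pathway protein ratio, community size
# classes, overlap/variation reports against a baseline clustering, and the
# observability x side-information grid experiment driver.

#' Normalized mutual information between two partitions
#'
#' `2 I(p;q) / (H(p) + H(q))` with natural-log entropies from the joint
#' contingency table (the common community-detection convention).  When both
#' partitions are a single community both entropies vanish and the partitions
#' are identical, so the value is defined as 1.  `"max"` and `"sqrt"`
#' normalizations (`I/max(H)`, `I/sqrt(H1 H2)`) are available for comparison.
#'
#' @param p,q Named character vectors over the same node universe.
#' @param variant Normalization; default `"arithmetic"`.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(p, q, variant = c("arithmetic", "max", "sqrt")) {
  variant <- match.arg(variant)
  if (!setequal(names(p), names(q))) {
    stop("partitions must cover the same node universe")
  }
  q <- q[names(p)]
  tab <- table(unname(p), unname(q))
  n <- sum(tab)
  pj <- tab / n
  rowm <- rowSums(pj)
  colm <- colSums(pj)
  h1 <- -sum(ifelse(rowm > 0, rowm * log(rowm), 0))
  h2 <- -sum(ifelse(colm > 0, colm * log(colm), 0))
  if (h1 == 0 && h2 == 0) return(1)
  outer_pq <- outer(rowm, colm)
  pos <- pj > 0
  mi <- sum(pj[pos] * log(pj[pos] / outer_pq[pos]))
  denom <- switch(variant,
                  arithmetic = (h1 + h2) / 2,
                  max = max(h1, h2),
                  sqrt = sqrt(h1 * h2))
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Pairwise information-retrieval metrics for a clustering
#'
#' The default `"pairs"` scheme scores all unordered node pairs (Rand-style
#' co-membership): a true positive is a pair together in both the truth and
#' the detected partition, a false positive is together only in the detected
#' one, a false negative together only in the truth.  The `"node_majority"`
#' alternative maps every detected community to the plurality truth label of
#' its members (ties to the lexicographically smallest label) and scores
#' per-node label agreement, with precision/sensitivity/F1 macro-averaged
#' over truth classes.
#'
#' @param truth,detected Named character vectors over the same universe of at
#'   least 2 nodes.
#' @param scheme Either `"pairs"` (default) or `"node_majority"`.
#' @return Named numeric vector `accuracy`, `precision`, `sensitivity`, `f1`.
#'   Ratios with a zero denominator are reported as 0 and flagged in the
#'   `"undefined"` attribute.
#' @export
pairwise_ir_metrics <- function(truth, detected,
                                scheme = c("pairs", "node_majority")) {
  scheme <- match.arg(scheme)
  if (!setequal(names(truth), names(detected))) {
    stop("partitions must cover the same node universe")
  }
  if (length(truth) < 2) stop("need at least 2 nodes to form pairs")
  detected <- detected[names(truth)]

  if (scheme == "pairs") {
    tab <- table(unname(truth), unname(detected))
    choose2 <- function(x) sum(x * (x - 1) / 2)
    tp <- choose2(tab)
    same_det <- choose2(colSums(tab))
    same_tru <- choose2(rowSums(tab))
    total <- choose2(sum(tab))
    fp <- same_det - tp
    fn <- same_tru - tp
    tn <- total - tp - fp - fn
    undefined <- character()
    precision <- if (tp + fp > 0) tp / (tp + fp) else {
      undefined <- c(undefined, "precision"); 0
    }
    sensitivity <- if (tp + fn > 0) tp / (tp + fn) else {
      undefined <- c(undefined, "sensitivity"); 0
    }
    f1 <- if (precision + sensitivity > 0) {
      2 * precision * sensitivity / (precision + sensitivity)
    } else {
      undefined <- c(undefined, "f1"); 0
    }
    out <- c(accuracy = (tp + tn) / total, precision = precision,
             sensitivity = sensitivity, f1 = f1)
    attr(out, "undefined") <- undefined
    return(out)
  }

  # node_majority: label each detected community by its plurality truth label
  pred <- vapply(split(unname(truth), unname(detected)), function(lbls) {
    cnt <- table(lbls)
    radix_sort(names(cnt)[cnt == max(cnt)])[1]
  }, character(1))
  predicted <- unname(pred[unname(detected)])
  classes <- radix_sort(unique(unname(truth)))
  prec <- sens <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(predicted == cl & truth == cl)
    prec[i] <- if (sum(predicted == cl) > 0) tp / sum(predicted == cl) else 0
    sens[i] <- tp / sum(truth == cl)
  }
  precision <- mean(prec)
  sensitivity <- mean(sens)
  f1 <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0
  out <- c(accuracy = mean(predicted == unname(truth)), precision = precision,
           sensitivity = sensitivity, f1 = f1)
  attr(out, "undefined") <- character()
  out
}

#' Pathway protein ratio of detected communities
#'
#' Each detected community is assigned the plurality label among its
#' annotated members (counting every label of multi-label nodes; ties go to
#' the lexicographically smallest label).  Its ratio is the fraction of all
#' members carrying the assigned label.  Communities without any annotated
#' member are unassigned, excluded from the mean.
#'
#' @param detected Named character vector (node -> community id).
#' @param annotations Named list (node -> labels), e.g. phytohormone pathway
#'   annotations.
#' @return Data frame with columns `community`, `size`, `label`,
#'   `n_matching`, `ratio`, one row per assigned community; the mean ratio is
#'   attached as attribute `"mean_ratio"`.
#' @export
pathway_protein_ratio <- function(detected, annotations) {
  comms <- radix_sort(unique(unname(detected)))
  rows <- lapply(comms, function(cm) {
    members <- names(detected)[detected == cm]
    lbls <- unlist(annotations[intersect(members, names(annotations))],
                   use.names = FALSE)
    if (length(lbls) == 0) return(NULL)
    cnt <- table(lbls)
    lab <- radix_sort(names(cnt)[cnt == max(cnt)])[1]
    n_match <- sum(vapply(members, function(v) {
      lab %in% annotations[[v]]
    }, logical(1)))
    data.frame(community = cm, size = length(members), label = lab,
               n_matching = n_match, ratio = n_match / length(members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(community = character(), size = integer(), label = character(),
               n_matching = integer(), ratio = numeric(),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  attr(out, "mean_ratio") <- if (nrow(out)) mean(out$ratio) else NA_real_
  out
}

#' Count communities by size class
#'
#' Small communities have size <= 3, motifs 3 < size <= 5 (the smallest
#' functional units), and modules size > 5 (larger functional groups).
#'
#' @param detected Named character vector (node -> community id).
#' @return Named integer vector `n_small`, `n_motif`, `n_module`.
#' @export
size_classes <- function(detected) {
  sizes <- as.integer(table(unname(detected)))
  c(n_small = sum(sizes <= 3),
    n_motif = sum(sizes > 3 & sizes <= 5),
    n_module = sum(sizes > 5))
}

#' Overlap and variation of detected communities against a baseline
#'
#' For every baseline community B, finds the detected community D with the
#' largest intersection (ties to the smallest community id) and reports the
#' overlap (conservation) ratio `|D n B| / |B|` and the normalized variation
#' `|D \ B| / |B|` (0 means every protein of D is a member of B).  Also
#' reported, per baseline community: how many detected communities intersect
#' it and both the union size and the summed size of those communities.
#' Matched communities more than five times the baseline size are flagged
#' `untestable` and excluded from the aggregate means.
#'
#' @param detected,baseline Named character vectors; node universes may
#'   differ, intersections are computed on shared nodes.
#' @return Data frame, one row per baseline community, with aggregate means
#'   (over testable rows) in attribute `"aggregate"`.
#' @export
overlap_variation <- function(detected, baseline) {
  det_comms <- split(names(detected), unname(detected))
  rows <- lapply(radix_sort(unique(unname(baseline))), function(bid) {
    B <- names(baseline)[baseline == bid]
    inter <- vapply(det_comms, function(D) length(intersect(D, B)), integer(1))
    hits <- inter[inter > 0]
    if (length(hits) == 0) {
      best_id <- NA_character_; best_size <- NA_integer_; best_inter <- 0L
      ov <- 0; va <- 0; n_over <- 0L; union_size <- 0L; sum_size <- 0L
      untestable <- FALSE
    } else {
      best_id <- radix_sort(names(hits)[hits == max(hits)])[1]
      D <- det_comms[[best_id]]
      best_size <- length(D)
      best_inter <- length(intersect(D, B))
      ov <- best_inter / length(B)
      va <- length(setdiff(D, B)) / length(B)
      n_over <- length(hits)
      union_size <- length(unique(unlist(det_comms[names(hits)])))
      sum_size <- sum(lengths(det_comms[names(hits)]))
      untestable <- best_size > 5 * length(B)
    }
    data.frame(baseline = bid, baseline_size = length(B),
               matched = best_id, matched_size = best_size,
               intersection = best_inter,
               overlap_ratio = ov, variation_ratio = va,
               n_overlapping = n_over,
               union_overlap_size = union_size,
               sum_overlap_size = sum_size,
               untestable = untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  testable <- out[!out$untestable & !is.na(out$matched), , drop = FALSE]
  attr(out, "aggregate") <- c(
    mean_overlap = if (nrow(testable)) mean(testable$overlap_ratio) else NA_real_,
    mean_variation = if (nrow(testable)) mean(testable$variation_ratio) else NA_real_)
  out
}

#' Experiment configuration for the benchmark grid
#'
#' @param block_sizes,p_in,p_out,seed As in [sbm_config()].
#' @param obs_grid Observability fractions; default the benchmark's
#'   `0.1, 0.2, ..., 1.0`.
#' @param si_grid Side-information fractions (of observed nodes); default
#'   `0, 0.1, ..., 1.0`.
#' @param corrupt_grid Fractions of the side information to corrupt; default
#'   no corruption.
#' @param repeats Number of independent network instances per grid cell
#'   (default 20).
#' @param laziness,curvature_threshold Passed to [detection_config()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(block_sizes = sbm_benchmark_config()$block_sizes,
                              p_in = 0.10, p_out = 0.005,
                              obs_grid = seq(0.1, 1, by = 0.1),
                              si_grid = seq(0, 1, by = 0.1),
                              corrupt_grid = 0,
                              repeats = 20L, seed = 1L,
                              laziness = 0, curvature_threshold = 0) {
  stopifnot(all(obs_grid > 0), all(obs_grid <= 1),
            all(si_grid >= 0), all(si_grid <= 1),
            all(corrupt_grid >= 0), all(corrupt_grid <= 1),
            repeats >= 1)
  structure(list(block_sizes = as.integer(block_sizes), p_in = p_in,
                 p_out = p_out, obs_grid = obs_grid, si_grid = si_grid,
                 corrupt_grid = corrupt_grid, repeats = as.integer(repeats),
                 seed = as.integer(seed), laziness = laziness,
                 curvature_threshold = curvature_threshold),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognised keys match the arguments of [experiment_config()].
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(experiment_config, vals)
}

#' Run the observability x side-information grid experiment
#'
#' For every repeat, one SBM instance is generated; for every observability
#' fraction the instance is partially observed; for every side-information
#' fraction ground-truth labels are sampled (and corrupted when requested),
#' detection runs, and both the final and the maximum-modularity partitions
#' are scored by NMI against the ground truth restricted to observed nodes.
#' Fully seeded: the same configuration always yields the same result.
#'
#' @param config An [experiment_config()].
#' @param verbose Print one progress line per repeat.
#' @return A list of class `grid_result`: `rows` (one row per repeat x cell x
#'   partition kind) and `summary` (mean and sd of NMI per cell and kind).
#' @export
run_grid <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dcfg_base <- detection_config(curvature_threshold = config$curvature_threshold,
                                laziness = config$laziness)
  rows <- list()
  for (r in seq_len(config$repeats)) {
    inst_seed <- substream_seed(config$seed, 1000L + r)
    sbm <- generate_sbm(sbm_config(config$block_sizes, config$p_in,
                                   config$p_out, seed = inst_seed))
    for (io in seq_along(config$obs_grid)) {
      f_obs <- config$obs_grid[io]
      inst <- observe(sbm$network, sbm$truth, f_obs,
                      seed = substream_seed(inst_seed, 100L + io))
      for (is in seq_along(config$si_grid)) {
        f_si <- config$si_grid[is]
        si0 <- sample_side_info(inst, f_si,
                                seed = substream_seed(inst_seed, 200L + is))
        for (ic in seq_along(config$corrupt_grid)) {
          f_cor <- config$corrupt_grid[ic]
          si <- if (f_cor > 0 && length(si0) > 0) {
            corrupt_side_info(si0, inst$truth, f_cor,
                              seed = substream_seed(inst_seed, 300L + ic))
          } else si0
          tr <- detect(inst$graph, side_info = si, config = dcfg_base)
          for (kind in c("final", "mm")) {
            part <- if (kind == "final") tr$final_partition else tr$mm_partition
            rows[[length(rows) + 1L]] <- data.frame(
              observed_fraction = f_obs, si_fraction = f_si,
              corrupt_fraction = f_cor, rep = r, kind = kind,
              nmi = nmi(inst$truth, part), stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (verbose) message(sprintf("repeat %d/%d done", r, config$repeats))
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  summary <- stats::aggregate(
    nmi ~ observed_fraction + si_fraction + corrupt_fraction + kind,
    data = rows,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  summary <- cbind(summary[, 1:4],
                   mean_nmi = summary$nmi[, "mean"],
                   sd_nmi = summary$nmi[, "sd"])
  summary <- summary[order(summary$observed_fraction, summary$si_fraction,
                           summary$corrupt_fraction, summary$kind), ]
  rownames(summary) <- NULL
  structure(list(rows = rows, summary = summary, config = config),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d rows over %d x %d x %d grid, %d repeat(s)\n",
              nrow(x$rows), length(x$config$obs_grid),
              length(x$config$si_grid), length(x$config$corrupt_grid),
              x$config$repeats))
  print(utils::head(x$summary, 12))
  invisible(x)
}
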