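#' Run the full study pipeline
#'
#' Orchestrates the analysis end-to-end in the study's order: (simulate or
#' load) each subject, then common-average re-reference, 2-46 Hz zero-phase
#' band-pass, 1-s epoching, |z| > 2 epoch rejection, Welch relative band
#' power, per-band ciPLV connectivity -- and finally group statistics:
#' cluster-based permutation correction for the electrode power maps and
#' edge-wise permutation tests with BH-FDR for connectivity.  Subjects are
#' processed one at a time, so memory stays flat in the number of subjects.
#'
#' @param config Either a `study_config` (simulation mode), or a full
#'   pipeline configuration list with elements `simulate` (a `study_config`)
#'   or `data` (data.frame/list with `path` and `group` per subject), and
#'   optional sections `preprocess` (`f_lo`, `f_hi`, `epoch_len_s`,
#'   `z_thresh`), `spectral` (`window_len_s`, `overlap`, `window`),
#'   `connectivity` (`metric`, `bands`), `stats` (`n_perm`, `cluster_alpha`,
#'   `q`, `adjacency_threshold`, `seed`).
#' @param out_dir Optional output directory for machine-readable artifacts
#'   (TSV tables and a JSON report).
#' @param verbose Print per-stage progress counts.
#' @return A `study_report`: per-band group-mean relative power, cluster
#'   results for the power maps, edge-wise connectivity statistics, node
#'   strength group means, preprocessing counts, and provenance (seed,
#'   config hash, package version).
#' @export
run_study <- function(config, out_dir = NULL, verbose = FALSE) {
  if (inherits(config, "study_config")) config <- list(simulate = config)
  prep <- utils::modifyList(list(f_lo = 2, f_hi = 46, epoch_len_s = 1,
                          z_thresh = 2), config$preprocess %||% list())
  spec <- utils::modifyList(list(window_len_s = 2, overlap = 0.5,
                          window = "hamming"), config$spectral %||% list())
  conn <- utils::modifyList(list(metric = "ciplv",
                          bands = band_scheme()$name),
                     config$connectivity %||% list())
  # n_perm_edges may exceed n_perm: with B permutations the smallest
  # attainable p is 1/(B+1), and BH across the 2016 edges cannot reject at
  # q = 0.05 unless ~ 2016/(0.05 (B+1)) edges reach that floor, so the
  # edge-wise test needs a finer p resolution than the max-statistic
  # cluster test does.
  stat <- utils::modifyList(list(n_perm = 50000, n_perm_edges = NULL,
                          cluster_alpha = 0.05, q = 0.05,
                          adjacency_threshold = 0.5, seed = 1),
                     config$stats %||% list())
  if (is.null(stat$n_perm_edges)) stat$n_perm_edges <- stat$n_perm
  scheme <- band_scheme()
  bands <- scheme[scheme$name %in% conn$bands, , drop = FALSE]
  if (nrow(bands) == 0) stop("no valid bands requested")

  sim_mode <- !is.null(config$simulate)
  if (sim_mode) {
    sc <- config$simulate
    stopifnot(inherits(sc, "study_config"))
    if (any(sc$n_per_group < 1))
      stop("empty group in simulation config: ",
           paste(names(sc$n_per_group)[sc$n_per_group < 1], collapse = ", "))
    plan <- subject_plan(sc)
    montage <- sc$montage
    seed_used <- sc$seed
  } else {
    dat <- as.data.frame(config$data)
    stopifnot(all(c("path", "group") %in% names(dat)))
    if (length(unique(dat$group)) != 2)
      stop("data mode needs exactly 2 groups, got: ",
           paste(unique(dat$group), collapse = ", "))
    if (any(table(dat$group) < 2))
      stop("group with fewer than 2 subjects: ",
           names(which(table(dat$group) < 2)))
    plan <- data.frame(group = dat$group,
                       id = basename(as.character(dat$path)),
                       path = dat$path, stringsAsFactors = FALSE)
    montage <- config$montage %||% biosemi64_montage()
    seed_used <- stat$seed
  }
  groups <- unique(plan$group)
  adjacency <- build_adjacency(montage, stat$adjacency_threshold)
  nch <- length(montage$labels)

  rp_all <- array(NA_real_, c(nch, nrow(bands), nrow(plan)),
                  dimnames = list(montage$labels, bands$name, plan$id))
  conn_all <- lapply(seq_len(nrow(bands)), function(i) vector("list",
                                                              nrow(plan)))
  names(conn_all) <- bands$name
  n_rejected <- integer(nrow(plan))

  for (i in seq_len(nrow(plan))) {
    rec <- if (sim_mode) {
      s <- simulate_sources(config$simulate, plan$group[i], plan$seed[i])
      project_to_sensors(s, montage, config$simulate)
    } else {
      r <- read_recording(plan$path[i])
      if (!identical(r$labels, montage$labels))
        stop("channel labels of ", plan$path[i], " do not match the montage")
      r
    }
    rec$subject_id <- plan$id[i]; rec$group <- plan$group[i]
    res <- process_subject(rec, bands, prep, spec, conn)
    rp_all[, , i] <- res$rp
    for (b in bands$name) conn_all[[b]][[i]] <- res$conn[[b]]
    n_rejected[i] <- res$n_rejected
    if (verbose)
      message(sprintf("[%d/%d] %s: %d epochs rejected", i, nrow(plan),
                      plan$id[i], res$n_rejected))
  }

  gA <- plan$group == groups[1]
  power_clusters <- list(); edge_stats <- list()
  rp_means <- list(); strength_means <- list()
  for (b in seq_len(nrow(bands))) {
    bn <- bands$name[b]
    mapsA <- rp_all[, b, gA, drop = TRUE]
    mapsB <- rp_all[, b, !gA, drop = TRUE]
    power_clusters[[bn]] <- cluster_permutation_test(
      mapsA, mapsB, adjacency, n_perm = stat$n_perm,
      seed = stat$seed + b, cluster_alpha = stat$cluster_alpha)
    edge_stats[[bn]] <- edgewise_group_test(
      conn_all[[bn]][gA], conn_all[[bn]][!gA],
      n_perm = stat$n_perm_edges, seed = stat$seed + 100 + b, q = stat$q)
    rp_means[[bn]] <- cbind(rowMeans(mapsA), rowMeans(mapsB))
    colnames(rp_means[[bn]]) <- groups
    st <- vapply(conn_all[[bn]], function(m) node_strength(m),
                 numeric(nch))
    strength_means[[bn]] <- cbind(rowMeans(st[, gA, drop = FALSE]),
                                  rowMeans(st[, !gA, drop = FALSE]))
    colnames(strength_means[[bn]]) <- groups
  }

  report <- structure(list(
    groups = groups, n_per_group = as.integer(table(plan$group)[groups]),
    bands = bands, labels = montage$labels,
    rp_group_means = rp_means,
    rp_subject = rp_all,
    power_clusters = power_clusters,
    edge_stats = edge_stats,
    node_strength_means = strength_means,
    n_epochs_rejected = stats::setNames(n_rejected, plan$id),
    provenance = list(seed = seed_used, stats_seed = stat$seed,
                      n_perm = stat$n_perm,
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("eegsync")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> groups ", paste(x$groups, collapse = "/"),
      " (n = ", paste(x$n_per_group, collapse = "/"), "), bands: ",
      paste(x$bands$name, collapse = ", "), "\n", sep = "")
  for (bn in x$bands$name) {
    sig_cl <- sum(vapply(x$power_clusters[[bn]]$clusters, `[[`,
                         numeric(1), "p") < 0.05)
    sig_e <- sum(x$edge_stats[[bn]]$significant)
    cat(sprintf("  %-6s power clusters p<0.05: %d; significant edges: %d\n",
                bn, sig_cl, sig_e))
  }
  invisible(x)
}

# Per-subject stage chain.  Numerically identical to the public-API chain
# rereference_average |> bandpass_filter |> segment_epochs |>
# reject_epochs_zscore |> welch_psd |> relative_band_power, plus
# analytic_phase |> segment_phases |> connectivity_matrix per band, but the
# padded forward FFT of the re-referenced record is computed once and reused
# by the broadband filter and every band's analytic signal (all share one
# FIR design contract, hence one tap count).
process_subject <- function(rec, bands, prep, spec, conn) {
  rec <- rereference_average(rec)
  fs <- rec$fs
  x <- t(matrix(rec$data[, 1, ], nrow = n_channels(rec)))
  m <- length(fir_bandpass(prep$f_lo, prep$f_hi, fs))
  pre <- fft_prepare(x, m)
  filtered_rec <- rec
  filtered_rec$data <- array(t(fft_apply(pre,
    fir_bandpass(prep$f_lo, prep$f_hi, fs))), dim(rec$data))
  epoched <- segment_epochs(filtered_rec, prep$epoch_len_s)
  rej <- reject_epochs_zscore(epoched, prep$z_thresh)
  ps <- welch_psd(rej$recording, spec$window_len_s, spec$overlap,
                  spec$window)
  rp <- relative_band_power(ps, band_scheme())
  rp <- rp[, bands$name, drop = FALSE]
  conn_out <- list()
  nc <- n_channels(rec)
  len <- as.integer(round(prep$epoch_len_s * fs))
  n_ep <- dim(rec$data)[3] %/% len
  keep <- rej$report$kept
  for (b in seq_len(nrow(bands))) {
    z <- fft_apply(pre, fir_bandpass(bands$f_lo[b], bands$f_hi[b], fs),
                   analytic = TRUE)
    mz <- Mod(z)
    conn_out[[bands$name[b]]] <- pl_epochs_cont(
      Re(z) / mz, Im(z) / mz, len, keep, conn$metric, 1e-12, rec$labels,
      c(bands$f_lo[b], bands$f_hi[b]))
  }
  list(rp = rp, conn = conn_out, n_rejected = rej$report$n_epochs_rejected)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # serialize a canonical JSON rendering (montage positions included)
  strip <- function(x) {
    if (inherits(x, "study_config")) x <- unclass(x)
    if (inherits(x, "montage")) x <- list(labels = x$labels,
                                          positions = round(x$positions, 9))
    if (is.list(x)) lapply(x, strip) else x
  }
  writeLines(jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = 9,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (bn in report$bands$name) {
    utils::write.table(
      data.frame(electrode = report$labels, report$rp_group_means[[bn]],
                 check.names = FALSE),
      file.path(out_dir, paste0("relative_power_", bn, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      as.data.frame(report$edge_stats[[bn]]),
      file.path(out_dir, paste0("edges_", bn, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cl <- lapply(report$power_clusters, function(cr)
    lapply(cr$clusters, function(c0) c0[c("members", "mass", "sign", "p")]))
  jsonlite::write_json(list(provenance = report$provenance,
                            n_epochs_rejected = report$n_epochs_rejected,
                            power_clusters = cl),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Score pipeline output against the simulation ground truth
#'
#' A planted power effect counts as detected when a significant cluster
#' (p < 0.05) of the correct direction contains at least one planted
#' electrode in the planted band.  A planted edge counts as detected when a
#' significant FDR-corrected edge of the correct direction connects the
#' graph neighbourhoods of its two anchor electrodes (spatial leakage makes
#' electrode-exact localization too strict).  The edge false-positive rate
#' is computed over edges outside all planted neighbourhood pairs.
#'
#' @param report A `study_report` produced from the simulation that produced
#'   `truth`.
#' @param truth Ground truth from [simulate_group_study()] / [ground_truth()].
#' @param adjacency The electrode adjacency used to define neighbourhoods
#'   (defaults to the packaged montage at threshold 0.5).
#' @return List with `power_detected`, `edge_detected` (logical per planted
#'   effect), `sensitivity`, `edge_fpr`, and the supporting counts.
#' @export
summarize_recovery <- function(report, truth,
                               adjacency = build_adjacency(
                                 biosemi64_montage())) {
  stopifnot(inherits(report, "study_report"))
  labels <- report$labels
  if (!all(unique(c(truth$power_effect$electrode,
                    truth$edge_effect$electrode_i,
                    truth$edge_effect$electrode_j)) %in% labels))
    stop("ground truth references electrodes absent from the report montage")
  nb <- neighbor_list(adjacency)
  hood <- function(el) {
    i <- match(el, adjacency$labels)
    adjacency$labels[c(i, nb[[i]])]
  }
  # power: per planted band, any significant cluster of correct sign
  # containing a planted electrode
  pe <- truth$power_effect
  power_detected <- logical(0)
  if (nrow(pe)) {
    for (bn in unique(pe$band)) {
      if (!bn %in% names(report$power_clusters)) {
        power_detected[bn] <- NA
        next
      }
      cr <- report$power_clusters[[bn]]
      want <- pe$electrode[pe$band == bn]
      sgn <- pe$sign[pe$band == bn][1]
      hit <- any(vapply(cr$clusters, function(cl) {
        cl$p < 0.05 &&
          cl$sign == (if (sgn > 0) "A>B" else "B>A") &&
          any(cl$members %in% want)
      }, logical(1)))
      power_detected[bn] <- hit
    }
  }
  # edges
  ee <- truth$edge_effect
  edge_detected <- logical(0)
  planted_pairs <- list()
  if (nrow(ee)) {
    for (r in seq_len(nrow(ee))) {
      bn <- ee$band[r]
      if (!bn %in% names(report$edge_stats)) {
        edge_detected[r] <- NA
        next
      }
      es <- report$edge_stats[[bn]]
      hi <- hood(ee$electrode_i[r]); hj <- hood(ee$electrode_j[r])
      in_hood <- (es$electrode_i %in% hi & es$electrode_j %in% hj) |
                 (es$electrode_i %in% hj & es$electrode_j %in% hi)
      dir_want <- if (ee$sign[r] > 0) "A>B" else "B>A"
      edge_detected[r] <- any(es$significant & in_hood &
                                es$direction == dir_want)
      planted_pairs[[r]] <- list(band = bn, mask = in_hood)
    }
  }
  # FPR over non-planted edges, per analysed band
  fp <- 0L; n_null <- 0L
  for (bn in names(report$edge_stats)) {
    es <- report$edge_stats[[bn]]
    excl <- rep(FALSE, nrow(es))
    for (pp in planted_pairs)
      if (!is.null(pp) && pp$band == bn) excl <- excl | pp$mask
    fp <- fp + sum(es$significant & !excl)
    n_null <- n_null + sum(!excl)
  }
  n_planted <- sum(!is.na(power_detected)) + sum(!is.na(edge_detected))
  sens <- if (n_planted > 0)
    (sum(power_detected, na.rm = TRUE) + sum(edge_detected, na.rm = TRUE)) /
      n_planted
  else NA_real_
  list(power_detected = power_detected, edge_detected = edge_detected,
       sensitivity = sens, edge_fpr = if (n_null > 0) fp / n_null else NA,
       n_false_positive_edges = fp, n_null_edges = n_null)
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Repeats the full simulate-analyse-score cycle over independent master
#' seeds: each repetition simulates a two-group study under the default
#' effect template (scaled to `duration_s` per subject), runs the pipeline
#' on the requested bands, and scores recovery of the planted effects with
#' [summarize_recovery()].  This is the package's validation harness: it
#' measures the detection rate of the planted centroparietal theta power
#' cluster and the planted theta edge, and the false-positive rate over
#' non-planted edges.
#'
#' @param n_seeds Number of independent simulated studies.
#' @param duration_s Recording length per subject (seconds).
#' @param n_perm Permutations per statistical test.
#' @param base_seed Base RNG seed; repetition `s` uses `base_seed + 1000*s`.
#' @param bands Bands to analyse (default `"theta"`).
#' @param config_fn Function(seed, duration_s) returning the `study_config`
#'   to simulate; defaults to the standard template.
#' @param verbose Print per-seed progress.
#' @return data.frame with one row per seed: `power_detected`,
#'   `edge_detected`, `edge_fpr`, `n_sig_edges`, and `pz_theta_d` (realized
#'   Cohen's d of theta relative power at Pz).
#' @export
recovery_experiment <- function(n_seeds = 20, duration_s = 60, n_perm = 999,
                                base_seed = 1, bands = "theta",
                                config_fn = NULL, verbose = FALSE) {
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    seed_s <- (base_seed + 1000 * s) %% (.Machine$integer.max - 1L)
    sc <- if (is.null(config_fn)) study_config(duration_s = duration_s,
                                               seed = seed_s)
          else config_fn(seed_s, duration_s)
    rep_s <- run_study(list(simulate = sc,
                            connectivity = list(metric = "ciplv",
                                                bands = bands),
                            stats = list(n_perm = n_perm,
                                         n_perm_edges = max(n_perm, 4999),
                                         seed = seed_s + 7)))
    rec <- summarize_recovery(rep_s, ground_truth(sc))
    gA <- seq_len(rep_s$n_per_group[1])
    pz_d <- if ("theta" %in% dimnames(rep_s$rp_subject)[[2]])
      cohens_d(rep_s$rp_subject["Pz", "theta", gA],
               rep_s$rp_subject["Pz", "theta", -gA])
    else NA_real_
    out[[s]] <- data.frame(
      seed = seed_s,
      power_detected = isTRUE(rec$power_detected[["theta"]]),
      edge_detected = isTRUE(rec$edge_detected[1]),
      edge_fpr = rec$edge_fpr,
      n_sig_edges = sum(vapply(rep_s$edge_stats,
                               function(e) sum(e$significant), integer(1))),
      pz_theta_d = pz_d)
    if (verbose)
      message(sprintf("seed %d: power %s edge %s fpr %.3f d %.2f", seed_s,
                      out[[s]]$power_detected, out[[s]]$edge_detected,
                      out[[s]]$edge_fpr, out[[s]]$pz_theta_d))
  }
  do.call(rbind, out)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a structured YAML file with the sections accepted by
#' [run_study()]; the `simulate` section is passed to [study_config()]
#' (table-like fields `sources`, `power_effects`, `couplings` may be given
#' as lists of records).
#'
#' @param path Path to a YAML file.
#' @return A pipeline configuration list.
#' @export
load_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    to_df <- function(x) if (is.null(x)) NULL else
      do.call(rbind, lapply(x, function(r) as.data.frame(r,
                                          stringsAsFactors = FALSE)))
    args <- list()
    if (!is.null(s$n_per_group)) args$n_per_group <- unlist(s$n_per_group)
    for (f in c("duration_s", "fs", "noise_exponent", "snr", "subject_sd",
                "leakage_width", "phase_walk_sd", "sensor_rms_uV", "seed"))
      if (!is.null(s[[f]])) args[[f]] <- s[[f]]
    for (f in c("sources", "power_effects", "couplings"))
      if (!is.null(s[[f]])) args[[f]] <- to_df(s[[f]])
    if (!is.null(s$montage)) args$montage <- load_montage(s$montage)
    cfg$simulate <- do.call(study_config, args)
  }
  cfg
}
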