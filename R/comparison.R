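# End-to-end comparison of conformational ensembles: one or more systems
# (e.g. a wild-type VHH and its humanized variants) are encoded into PB
# matrices and summarised into per-position flexibility tables, pairwise
# delta-Neq / delta-PB series, region summaries, PB logos for flagged
# windows and an optional humanization mutation audit.

#' Assemble and validate a comparison configuration
#'
#' @param systems named list of systems. Each entry is an [ensemble], a path
#'   to a (multi-model) PDB file, or a synthetic spec: a list with
#'   `profiles` (L x 16 matrix) and optional `n_frames`, `noise`,
#'   `letters_m`.
#' @param regions a [region_map()]; defaults to the built-in 121-residue
#'   scheme when every system has 121 residues, otherwise must be supplied.
#' @param sequences optional named character list of residue sequences; the
#'   first entry is treated as the wild type and each other entry is diffed
#'   against it for the mutation audit.
#' @param exclude_extremities positions dropped at each terminus for
#'   correlation summaries.
#' @param delta_pb_threshold per-position delta-PB at or above which a
#'   position is flagged as conformationally different (default 0.5, i.e. a
#'   quarter of occurrences differing).
#' @param seed RNG seed used when synthetic specs are materialised.
#' @return a `comparison_config` list.
#' @export
comparison_config <- function(systems, regions = NULL, sequences = NULL,
                              exclude_extremities = 3L,
                              delta_pb_threshold = 0.5, seed = NULL) {
  stopifnot(is.list(systems), length(systems) >= 1)
  if (is.null(names(systems)) || any(names(systems) == "")) {
    stop("every system must be named")
  }
  structure(list(systems = systems, regions = regions, sequences = sequences,
                 exclude_extremities = as.integer(exclude_extremities),
                 delta_pb_threshold = delta_pb_threshold, seed = seed),
            class = "comparison_config")
}

.load_system <- function(x, name, seed) {
  if (inherits(x, "ensemble")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("unreadable ensemble for system '", name,
                              "': ", x)
    return(read_ensemble(x))
  }
  if (is.list(x) && !is.null(x$profiles)) {
    return(make_ensemble(x$profiles, n_frames = x$n_frames %||% 100L,
                         noise = x$noise %||% 5, seed = seed,
                         letters_m = x$letters_m))
  }
  stop("system '", name, "' is neither an ensemble, a path nor a synthetic spec")
}

# contiguous runs of flagged positions -> list of integer windows
.runs <- function(positions) {
  if (length(positions) == 0) return(list())
  br <- c(0, which(diff(positions) != 1), length(positions))
  lapply(seq_len(length(br) - 1), function(i) {
    positions[(br[i] + 1):br[i + 1]]
  })
}

#' Run the full multi-system comparison
#'
#' @param config a [comparison_config()].
#' @return a `comparison_report` list: `per_position` (one data.frame per
#'   system: position, region, rmsf, neq, flexibility class), `per_region`
#'   (region means of Neq and RMSF per system), `pairwise` (per system pair:
#'   per-position delta-Neq / delta-PB, flagged positions, flagged windows),
#'   `correlations` (pairwise RMSF and Neq correlations, extremities
#'   excluded), `logos` (PB logo stacks of every flagged window in both
#'   systems of the pair), `mutation_audit` (when sequences are given) and
#'   `log` (run metadata: frame counts, Z counts, seed, threshold).
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "comparison_config"))
  sys_names <- names(config$systems)
  ens <- mapply(.load_system, config$systems, sys_names,
                MoreArgs = list(seed = config$seed), SIMPLIFY = FALSE)
  L <- vapply(ens, n_residues, integer(1))
  if (length(unique(L)) > 1) {
    i <- which(L != L[1])[1]
    stop("systems '", sys_names[1], "' (", L[1], " residues) and '",
         sys_names[i], "' (", L[i], " residues) differ in length")
  }
  L <- L[1]
  regions <- config$regions %||%
    (if (L == 121L) default_region_map() else
       stop("no region map supplied and length != 121"))
  if (regions$end[nrow(regions)] != L) stop("region map does not cover 1..", L)

  pbm <- lapply(ens, encode_ensemble)
  prof <- lapply(pbm, pb_profiles)
  neqs <- lapply(prof, neq)
  rmsfs <- lapply(ens, function(e) {
    if (n_frames(e) >= 2) rmsf(e) else rep(NA_real_, L)
  })
  reg_names <- region_of(seq_len(L), regions)

  per_position <- lapply(sys_names, function(s) {
    data.frame(system = s, position = seq_len(L), region = reg_names,
               rmsf = rmsfs[[s]], neq = neqs[[s]],
               class = as.character(classify_flexibility(neqs[[s]])))
  })
  names(per_position) <- sys_names

  per_region <- do.call(rbind, lapply(sys_names, function(s) {
    cbind(system = s,
          region_summary(neqs[[s]], regions)[, c("region", "mean")],
          rmsf_mean = region_summary(rmsfs[[s]], regions)$mean)
  }))
  names(per_region)[3] <- "neq_mean"

  pairwise <- list(); logos <- list(); correlations <- NULL
  if (length(ens) >= 2) {
    pairs <- utils::combn(sys_names, 2, simplify = FALSE)
    for (pr in pairs) {
      key <- paste(pr, collapse = " vs ")
      dpb <- delta_pb(prof[[pr[1]]], prof[[pr[2]]])
      dneq <- delta_neq(neqs[[pr[1]]], neqs[[pr[2]]])
      flagged <- which(!is.na(dpb) & dpb >= config$delta_pb_threshold)
      pairwise[[key]] <- list(
        table = data.frame(position = seq_len(L), region = reg_names,
                           delta_neq = dneq, delta_pb = dpb),
        flagged_positions = flagged,
        flagged_windows = .runs(flagged))
      for (w in pairwise[[key]]$flagged_windows) {
        wkey <- paste0(key, " @", min(w), "-", max(w))
        logos[[wkey]] <- lapply(pr, function(s) pb_logo(pbm[[s]], w))
        names(logos[[wkey]]) <- pr
      }
      correlations <- rbind(correlations, data.frame(
        pair = key,
        rmsf_cor = tryCatch(
          correlate(rmsfs[[pr[1]]], rmsfs[[pr[2]]], exclude_extremities = TRUE,
                    n_excluded = config$exclude_extremities),
          error = function(e) NA_real_, warning = function(w) NA_real_),
        neq_cor = tryCatch(
          correlate(neqs[[pr[1]]], neqs[[pr[2]]], exclude_extremities = TRUE,
                    n_excluded = config$exclude_extremities),
          error = function(e) NA_real_, warning = function(w) NA_real_)))
    }
  }

  mutation_audit <- NULL
  if (!is.null(config$sequences) && length(config$sequences) >= 2) {
    wt <- config$sequences[[1]]
    mutation_audit <- do.call(rbind, lapply(
      names(config$sequences)[-1], function(v) {
        muts <- diff_sequences(wt, config$sequences[[v]])
        if (nrow(muts) == 0) return(NULL)
        ann <- classify_mutations(muts, regions)
        rownames(ann) <- NULL
        cbind(variant = v, ann,
              percent = rep(percent_mutated(muts, L), nrow(ann)))
      }))
  }

  structure(list(
    per_position = per_position, per_region = per_region,
    pairwise = pairwise, correlations = correlations, logos = logos,
    mutation_audit = mutation_audit, regions = regions,
    log = list(systems = sys_names,
               n_frames = vapply(ens, n_frames, integer(1)),
               n_residues = L,
               n_unassigned = vapply(pbm, function(m) sum(m == PB_UNDEF),
                                     numeric(1)),
               seed = config$seed,
               delta_pb_threshold = config$delta_pb_threshold,
               exclude_extremities = config$exclude_extremities)),
    class = "comparison_report")
}

#' Write a comparison report to disk
#'
#' Canonical outputs are TSV/JSON: `per_position.tsv` (all systems, long
#' format), `per_region.tsv`, `pairwise.tsv` (header-only when there is a
#' single system), `logos.json`, `mutations.tsv` (when audited) and
#' `run_log.txt`. Reruns of the same report are byte-identical. On an I/O
#' failure, files already written by this call are removed.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  fmt <- function(x) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) {
      ifelse(is.na(v), "NA", formatC(v, digits = 6, format = "g"))
    })
    x
  }
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(fmt(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, p)
  }
  tryCatch({
    emit(do.call(rbind, report$per_position), "per_position.tsv")
    emit(report$per_region, "per_region.tsv")
    pw <- data.frame(pair = character(0), position = integer(0),
                     region = character(0), delta_neq = numeric(0),
                     delta_pb = numeric(0))
    for (key in names(report$pairwise)) {
      pw <- rbind(pw, cbind(pair = key, report$pairwise[[key]]$table))
    }
    emit(pw, "pairwise.tsv")
    if (!is.null(report$mutation_audit)) {
      emit(report$mutation_audit, "mutations.tsv")
    }
    p <- file.path(dir, "logos.json")
    jsonlite::write_json(report$logos, p, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    written <- c(written, p)
    p <- file.path(dir, "run_log.txt")
    lg <- report$log
    writeLines(c(
      paste("systems:", paste(lg$systems, collapse = ", ")),
      paste("n_frames:", paste(lg$n_frames, collapse = ", ")),
      paste("n_residues:", lg$n_residues),
      paste("unassigned (Z) cells per system:",
            paste(lg$n_unassigned, collapse = ", ")),
      paste("seed:", lg$seed %||% "none"),
      paste("delta_pb_threshold:", lg$delta_pb_threshold),
      paste("exclude_extremities:", lg$exclude_extremities),
      if (!is.null(report$correlations)) {
        paste0("correlation ", report$correlations$pair, ": RMSF ",
               round(report$correlations$rmsf_cor, 3), ", Neq ",
               round(report$correlations$neq_cor, 3))
      }), p)
    written <- c(written, p)
  }, error = function(e) {
    unlink(written)
    stop("write_report failed (partial outputs removed): ",
         conditionMessage(e))
  })
  invisible(written)
}
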