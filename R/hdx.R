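#' A peptic peptide
#'
#' Residue numbers are 1-based and inclusive in pre-pro-protein numbering
#' (the A1 region spans residues 1238-1489). The number of exchangeable
#' backbone amides follows the field convention: peptide length minus one
#' (the N-terminal residue's amide back-exchanges too fast to measure)
#' minus the number of prolines at positions 2..length (prolines have no
#' backbone amide hydrogen).
#'
#' @param start,end First and last residue numbers, `end >= start`.
#' @param sequence Amino-acid sequence, one-letter code; length must equal
#'   `end - start + 1`.
#' @return An object of class `"hdx_peptide"` with derived
#'   `max_exchangeable`.
#' @export
hdx_peptide <- function(start, end, sequence) {
  .check_scalar(start, "start", positive = TRUE)
  .check_scalar(end, "end", positive = TRUE)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (end < start) stop("'end' must be >= 'start'", call. = FALSE)
  len <- as.integer(end - start + 1)
  if (nchar(sequence) != len) {
    stop(sprintf("sequence length %d does not match span %d-%d",
                 nchar(sequence), start, end), call. = FALSE)
  }
  aa <- strsplit(toupper(sequence), "")[[1L]]
  n_pro <- sum(aa[-1L] == "P")
  structure(list(start = start, end = end, sequence = sequence,
                 max_exchangeable = as.integer(len - 1L - n_pro)),
            class = "hdx_peptide")
}

#' Relative deuterium uptake as a percentage
#'
#' `100 * uptake / max_exchangeable`, optionally normalized by the D2O
#' fraction of the labeling buffer (so that 100% means full exchange of
#' every available amide at the achievable deuterium level). Uptake values
#' are relative (not corrected for back exchange).
#'
#' @param uptake Deuterium uptake in Da.
#' @param peptide An [hdx_peptide()].
#' @param normalize_d2o Divide by the D2O fraction (default `FALSE`).
#' @param d2o_fraction D2O fraction of the labeling buffer (default 0.933).
#' @return Percent of available amide hydrogens exchanged.
#' @export
relative_uptake_percent <- function(uptake, peptide, normalize_d2o = FALSE,
                                    d2o_fraction = 0.933) {
  stopifnot(inherits(peptide, "hdx_peptide"))
  if (peptide$max_exchangeable == 0L) {
    stop("peptide has no exchangeable amides; percent uptake undefined",
         call. = FALSE)
  }
  denom <- peptide$max_exchangeable * (if (normalize_d2o) d2o_fraction else 1)
  100 * uptake / denom
}

#' Sequence coverage and redundancy of a peptide map
#'
#' Coverage is the percentage of residues in the region covered by at
#' least one peptide. Redundancy is the average peptide depth over the
#' whole region: the sum over peptides of their overlap with the region,
#' divided by the region length (uncovered residues contribute zero; set
#' `covered_only = TRUE` to average over covered residues instead).
#'
#' @param peptides List of [hdx_peptide()] objects.
#' @param region_start,region_end Region bounds, residues, inclusive.
#' @param covered_only Average redundancy over covered residues only.
#' @return A list with `coverage` (percent) and `redundancy` (x-fold).
#' @export
coverage_and_redundancy <- function(peptides, region_start, region_end,
                                    covered_only = FALSE) {
  stopifnot(length(peptides) >= 1L,
            all(vapply(peptides, inherits, TRUE, "hdx_peptide")))
  .check_scalar(region_start, "region_start", positive = TRUE)
  .check_scalar(region_end, "region_end", positive = TRUE)
  if (region_end < region_start) stop("empty region", call. = FALSE)
  residues <- region_start:region_end
  depth <- integer(length(residues))
  outside <- 0L
  for (p in peptides) {
    if (p$end < region_start || p$start > region_end) {
      outside <- outside + 1L
      next
    }
    sel <- residues >= p$start & residues <= p$end
    depth[sel] <- depth[sel] + 1L
  }
  if (outside > 0L) {
    warning(outside, " peptide(s) entirely outside the region ignored",
            call. = FALSE)
  }
  covered <- depth > 0L
  list(coverage = 100 * mean(covered),
       redundancy = if (covered_only) {
         if (any(covered)) mean(depth[covered]) else 0
       } else mean(depth))
}

#' An HDX experiment for one construct
#'
#' @param construct Construct label.
#' @param measurements A data.frame with columns `pep_start`, `pep_end`,
#'   `pep_sequence`, `timepoint_s`, `replicate`, `uptake_Da`.
#' @param d2o_fraction D2O fraction of the labeling buffer (default 0.933).
#' @return An object of class `"hdx_experiment"`; the `peptides` element
#'   holds the distinct [hdx_peptide()] objects.
#' @export
hdx_experiment <- function(construct, measurements, d2o_fraction = 0.933) {
  stopifnot(is.character(construct), length(construct) == 1L,
            is.data.frame(measurements))
  req <- c("pep_start", "pep_end", "pep_sequence", "timepoint_s",
           "replicate", "uptake_Da")
  miss <- setdiff(req, names(measurements))
  if (length(miss) > 0L) {
    stop("measurements missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- unique(measurements[, c("pep_start", "pep_end", "pep_sequence")])
  peptides <- lapply(seq_len(nrow(key)), function(i) {
    hdx_peptide(key$pep_start[i], key$pep_end[i], key$pep_sequence[i])
  })
  # noise floor / ceiling sanity on the uptake values
  for (i in seq_len(nrow(key))) {
    sel <- measurements$pep_start == key$pep_start[i] &
      measurements$pep_end == key$pep_end[i]
    u <- measurements$uptake_Da[sel]
    mx <- peptides[[i]]$max_exchangeable
    if (any(u < -0.5) || any(u > mx + 0.5)) {
      stop(sprintf(
        "uptake outside [-0.5, max_exchangeable + 0.5] Da for peptide %d-%d",
        key$pep_start[i], key$pep_end[i]), call. = FALSE)
    }
  }
  structure(list(construct = construct, measurements = measurements,
                 peptides = peptides, d2o_fraction = d2o_fraction,
                 timepoints = sort(unique(measurements$timepoint_s))),
            class = "hdx_experiment")
}

#' @export
print.hdx_experiment <- function(x, ...) {
  cat(sprintf("<hdx_experiment> %s: %d peptides, timepoints %s s\n",
              x$construct, length(x$peptides),
              paste(x$timepoints, collapse = "/")))
  invisible(x)
}

## replicate-averaged uptake per (peptide, timepoint), with replicate count
.average_uptake <- function(exp) {
  m <- exp$measurements
  key <- interaction(m$pep_start, m$pep_end, m$timepoint_s, drop = TRUE)
  agg <- do.call(rbind, lapply(split(m, key), function(d) {
    data.frame(pep_start = d$pep_start[1L], pep_end = d$pep_end[1L],
               pep_sequence = d$pep_sequence[1L],
               timepoint_s = d$timepoint_s[1L],
               uptake_Da = mean(d$uptake_Da), n_rep = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Pairwise HDX difference map between constructs
#'
#' Computes `delta = reference uptake - other uptake` on
#' replicate-averaged uptake for every peptide/timepoint shared by both
#' experiments. An entry is significant when `|delta|` strictly exceeds
#' the threshold (default 0.7 Da). The per-entry propagated uncertainty is
#' `repeatability * sqrt(1/nA + 1/nB)` from the per-measurement mass
#' repeatability. Peptides or timepoints present in only one experiment
#' are reported under `$not_shared`, not silently dropped.
#'
#' @param reference,other [hdx_experiment()] objects.
#' @param threshold Significance threshold in Da (strict `>`, default 0.7).
#' @param repeatability Per-measurement mass error in Da (default 0.15).
#' @return An object of class `"hdx_difference_map"`: `entries` data.frame
#'   (`pep_start`, `pep_end`, `timepoint_s`, `delta_Da`, `se_Da`,
#'   `significant`), `per_peptide` (summed |delta| over timepoints),
#'   `not_shared`, `threshold`, and the two labels.
#' @export
difference_map <- function(reference, other, threshold = 0.7,
                           repeatability = 0.15) {
  stopifnot(inherits(reference, "hdx_experiment"),
            inherits(other, "hdx_experiment"))
  .check_scalar(threshold, "threshold", positive = TRUE)
  a <- .average_uptake(reference)
  b <- .average_uptake(other)
  ka <- paste(a$pep_start, a$pep_end, a$timepoint_s)
  kb <- paste(b$pep_start, b$pep_end, b$timepoint_s)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) {
    stop("experiments share no peptide/timepoint combinations",
         call. = FALSE)
  }
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  delta <- a$uptake_Da[ia] - b$uptake_Da[ib]
  se <- repeatability * sqrt(1 / a$n_rep[ia] + 1 / b$n_rep[ib])
  entries <- data.frame(
    pep_start = a$pep_start[ia], pep_end = a$pep_end[ia],
    timepoint_s = a$timepoint_s[ia],
    delta_Da = delta, se_Da = se,
    significant = abs(delta) > threshold,
    stringsAsFactors = FALSE)
  entries <- entries[order(entries$pep_start, entries$pep_end,
                           entries$timepoint_s), ]
  rownames(entries) <- NULL

  pk <- interaction(entries$pep_start, entries$pep_end, drop = TRUE)
  per_pep <- do.call(rbind, lapply(split(entries, pk), function(d) {
    data.frame(pep_start = d$pep_start[1L], pep_end = d$pep_end[1L],
               sum_abs_delta_Da = sum(abs(d$delta_Da)),
               any_significant = any(d$significant),
               n_significant = sum(d$significant),
               stringsAsFactors = FALSE)
  }))
  per_pep <- per_pep[order(per_pep$pep_start, per_pep$pep_end), ]
  rownames(per_pep) <- NULL

  structure(list(reference_label = reference$construct,
                 other_label = other$construct,
                 entries = entries, per_peptide = per_pep,
                 not_shared = c(setdiff(ka, kb), setdiff(kb, ka)),
                 threshold = threshold),
            class = "hdx_difference_map")
}

#' @export
print.hdx_difference_map <- function(x, ...) {
  cat(sprintf("<hdx_difference_map> %s minus %s: %d entries, %d significant (|delta| > %.2g Da)\n",
              x$reference_label, x$other_label, nrow(x$entries),
              sum(x$entries$significant), x$threshold))
  invisible(x)
}
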