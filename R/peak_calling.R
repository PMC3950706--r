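# A simplified Poisson sliding-window enrichment caller with sample-swap
# empirical FDR, plus the two peak-selection filters (control-tag exclusion
# and FDR selection) that also apply to externally called peaks.

#' Parameters for the sliding-window caller
#'
#' @param genome_size Effective genome size in bp (required).
#' @param window Window width in bp.
#' @param step Window step in bp (`0 < step <= window`).
#' @param pvalue_cutoff Upper-tail Poisson p-value at which a window is
#'   considered enriched.
#' @param fdr_cutoff Default FDR cutoff carried along for downstream
#'   selection.
#' @return A `caller_params` list.
#' @export
caller_params <- function(genome_size, window = 300, step = 100,
                          pvalue_cutoff = 1e-5, fdr_cutoff = 0.001) {
  .chk(!missing(genome_size) && .is_scalar_num(genome_size) && genome_size > 0,
       "genome_size must be supplied and positive")
  .chk(.is_scalar_num(window) && window >= 1, "window must be >= 1")
  .chk(.is_scalar_num(step) && step > 0 && step <= window,
       "step must satisfy 0 < step <= window")
  .chk(.is_scalar_num(pvalue_cutoff) && pvalue_cutoff > 0 && pvalue_cutoff < 1,
       "pvalue_cutoff must lie in (0, 1)")
  .chk(.is_scalar_num(fdr_cutoff) && fdr_cutoff >= 0 && fdr_cutoff <= 1,
       "fdr_cutoff must lie in [0, 1]")
  structure(list(genome_size = genome_size, window = as.integer(window),
                 step = as.integer(step), pvalue_cutoff = pvalue_cutoff,
                 fdr_cutoff = fdr_cutoff),
            class = "caller_params")
}

# One direction of the scan: tile each chromosome carrying treatment tags,
# test window counts against lambda = max(genome-wide rate, scaled control),
# and merge overlapping significant windows into candidate peaks with
# p = min over member windows.
.window_scan <- function(treatment, control, params) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  n_t <- nrow(treatment)
  if (!n_t) return(empty)
  bg_lambda <- n_t / params$genome_size * params$window
  ratio <- if (!is.null(control) && nrow(control)) n_t / nrow(control) else 0
  res <- list()
  for (ch in sort(unique(treatment$chrom))) {
    fp <- treatment$five_prime[treatment$chrom == ch]
    starts <- seq.int(0L, max(fp), by = params$step)
    wins <- data.frame(chrom = ch, start = starts,
                       end = starts + params$window,
                       stringsAsFactors = FALSE)
    x <- .count_in_intervals(treatment, wins)
    lambda <- rep(bg_lambda, length(starts))
    if (ratio > 0) {
      cc <- .count_in_intervals(control, wins)
      lambda <- pmax(lambda, cc * ratio)
    }
    p <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
    keep <- which(p <= params$pvalue_cutoff & x > 0)
    if (!length(keep)) next
    ks <- starts[keep]
    ke <- ks + params$window
    kp <- p[keep]
    grp <- cumsum(c(1L, as.integer(ks[-1L] >= ke[-length(ke)])))
    res[[ch]] <- data.frame(
      chrom = ch,
      start = as.integer(tapply(ks, grp, min)),
      end = as.integer(tapply(ke, grp, max)),
      p = as.numeric(tapply(kp, grp, min)),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call enriched peaks with a Poisson sliding-window test
#'
#' Windows are tested against the larger of the genome-wide background rate
#' and the depth-scaled control count; overlapping significant windows are
#' merged into peaks. Each peak's empirical FDR is estimated by swapping
#' treatment and control: `fdr(p) = #(swap peaks with p' <= p) /
#' #(treatment peaks with p'' <= p)`, clipped to \[0, 1\].
#'
#' @param treatment Tag data frame (filtered upstream).
#' @param control Tag data frame used for the local lambda and the swap;
#'   `NULL` for background-only calling (swap FDR is then 0).
#' @param params A [caller_params()] object.
#' @param dataset_id Label stored in the output peaks.
#' @return A peak data frame with `score = -10*log10(p)` and `tag_count`
#'   filled by 5'-in-interval counting.
#' @export
call_peaks <- function(treatment, control = NULL, params,
                       dataset_id = NA_character_) {
  .chk(inherits(params, "caller_params"), "params must come from caller_params()")
  validate_tags(treatment)
  if (!is.null(control)) validate_tags(control)
  if (!nrow(treatment)) {
    warning("no treatment tags; returning zero peaks")
    return(peak_frame())
  }
  obs <- .window_scan(treatment, control, params)
  if (!nrow(obs)) return(peak_frame())
  swap_p <- if (!is.null(control) && nrow(control)) {
    .window_scan(control, treatment, params)$p
  } else numeric(0)
  sorted_obs <- sort(obs$p)
  sorted_swap <- sort(swap_p)
  n_swap_le <- findInterval(obs$p, sorted_swap)
  n_obs_le <- findInterval(obs$p, sorted_obs)
  fdr <- pmin(pmax(n_swap_le / n_obs_le, 0), 1)
  score <- ifelse(obs$p > 0, -10 * log10(obs$p), 3000)
  out <- peak_frame(chrom = obs$chrom, start = obs$start, end = obs$end,
                    score = score, fdr = fdr,
                    tag_count = .count_in_intervals(treatment, obs),
                    dataset_id = rep(dataset_id, nrow(obs)))
  out
}

#' Exclude peaks with high control-tag counts
#'
#' A peak is excluded when ANY supplied control library has strictly more
#' than `threshold` tags (5' ends) inside the peak interval; the default
#' reproduces the ">100 control tags" artifact rule.
#'
#' @param peaks A peak data frame.
#' @param control_tags A tag data frame, or a list of them (one per
#'   control library).
#' @param threshold Exclusion threshold (strict `>`).
#' @return List with disjoint `kept` and `excluded` peak frames whose
#'   union is the input.
#' @export
exclude_by_control <- function(peaks, control_tags, threshold = 100) {
  validate_peaks(peaks)
  .chk(.is_scalar_num(threshold) && threshold >= 0, "threshold must be >= 0")
  if (is.data.frame(control_tags)) control_tags <- list(control_tags)
  excl <- rep(FALSE, nrow(peaks))
  for (ct in control_tags) {
    validate_tags(ct)
    excl <- excl | (.count_in_intervals(ct, peaks) > threshold)
  }
  kept <- peaks[!excl, , drop = FALSE]
  excluded <- peaks[excl, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Select peaks by FDR
#'
#' Retains peaks with `fdr <= cutoff` (inclusive, matching the usual
#' "FDR of <= 0.001" phrasing).
#'
#' @param peaks A peak data frame; every peak must carry an `fdr`.
#' @param cutoff Inclusive FDR cutoff.
#' @return The retained peaks.
#' @export
filter_fdr <- function(peaks, cutoff = 0.001) {
  validate_peaks(peaks)
  .chk(.is_scalar_num(cutoff) && cutoff >= 0 && cutoff <= 1,
       "cutoff must lie in [0, 1]")
  .chk(!anyNA(peaks$fdr), "every peak must carry an fdr value")
  out <- peaks[peaks$fdr <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
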