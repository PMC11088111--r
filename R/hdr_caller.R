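#' Empirical quantile with linear interpolation
#'
#' The default quantile definition of mainstream statistical environments
#' (type 7: linear interpolation between order statistics). Non-finite
#' entries are excluded.
#'
#' @param values numeric vector with at least one finite value.
#' @param q quantile level in (0, 1).
#' @return The quantile value.
#' @export
quantile_threshold <- function(values, q) {
  stopifnot(length(q) == 1L, q > 0, q < 1)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values")
  unname(quantile(v, probs = q, type = 7))
}

#' Flag high-diversity windows by joint percentile thresholds
#'
#' A window is selected iff its FST lies strictly below the lower `q_fst`
#' genome-wide quantile and its pi lies strictly above the upper `q_pi`
#' quantile in *both* populations. Thresholds are computed genome-wide over
#' the retained windows (those with no missing statistic), the set the scan
#' itself uses; windows with any missing statistic are excluded and never
#' selected.
#'
#' @param ws window table from [window_summaries()].
#' @param q_fst lower quantile level for FST (default 0.05).
#' @param q_pi upper quantile level for pi (default 0.95).
#' @return `ws` with logical columns `retained` and `selected`; the realized
#'   thresholds are in attribute `thresholds`
#'   (`fst_cut`, `pi_cut_<pop1>`, `pi_cut_<pop2>`).
#' @export
select_hdr_windows <- function(ws, q_fst = 0.05, q_pi = 0.95) {
  pops <- attr(ws, "pops")
  if (is.null(pops)) stop("ws must come from window_summaries()")
  ws <- copy(as.data.table(ws))
  pi1 <- ws[[paste0("pi_", pops[1])]]
  pi2 <- ws[[paste0("pi_", pops[2])]]
  retained <- !(is.na(ws$fst) | is.na(pi1) | is.na(pi2) | is.na(ws$dxy))
  if (!any(retained)) stop("no retained windows")
  fst_cut <- quantile_threshold(ws$fst[retained], q_fst)
  pi_cut1 <- quantile_threshold(pi1[retained], q_pi)
  pi_cut2 <- quantile_threshold(pi2[retained], q_pi)
  ws[, retained := retained]
  ws[, selected := retained & ws$fst < fst_cut & pi1 > pi_cut1 &
        pi2 > pi_cut2]
  thr <- c(fst_cut = fst_cut, pi_cut1, pi_cut2)
  names(thr)[2:3] <- paste0("pi_cut_", pops)
  attr(ws, "thresholds") <- thr
  attr(ws, "pops") <- pops
  ws[]
}

#' Merge selected windows into high-diversity regions
#'
#' Maximal runs of selected windows, allowing up to `max_gap` unselected
#' windows inside a run, become regions. Windows are taken in (chrom, start)
#' order; gaps are counted in windows, and runs never cross contigs.
#'
#' @param ws output of [select_hdr_windows()].
#' @param max_gap maximum number of consecutive unselected windows bridged
#'   inside a region (default 0).
#' @return data.table of regions: `chrom`, `start`, `end`, `n_windows`
#'   (selected members), mean `fst`, mean pi per population, mean `dxy`
#'   (means over selected member windows).
#' @export
merge_windows_to_regions <- function(ws, max_gap = 0L) {
  pops <- attr(ws, "pops")
  if (is.null(pops) || !"selected" %in% names(ws))
    stop("ws must come from select_hdr_windows()")
  ws <- as.data.table(ws)
  setorder(ws, chrom, start)
  sel <- which(ws$selected)
  if (!length(sel)) {
    empty <- data.table(chrom = character(), start = integer(),
                        end = integer(), n_windows = integer(),
                        fst = numeric(),
                        pi_1 = numeric(), pi_2 = numeric(), dxy = numeric())
    setnames(empty, c("pi_1", "pi_2"), paste0("pi_", pops))
    return(empty)
  }
  new_region <- c(TRUE,
                  diff(sel) > max_gap + 1L |
                    ws$chrom[sel[-1]] != ws$chrom[sel[-length(sel)]])
  rid <- cumsum(new_region)
  p1 <- paste0("pi_", pops[1]); p2 <- paste0("pi_", pops[2])
  memb <- data.table(i = sel, region_id = rid)
  out <- memb[, {
    w <- ws[i]
    .(chrom = w$chrom[1], start = min(w$start), end = max(w$end),
      n_windows = .N, fst = mean(w$fst),
      pi_1 = mean(w[[p1]]), pi_2 = mean(w[[p2]]), dxy = mean(w$dxy))
  }, by = region_id][, region_id := NULL]
  setnames(out, c("pi_1", "pi_2"), c(p1, p2))
  out[]
}
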