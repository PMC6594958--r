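#' Gate germ-cell events on the lineage label against an unstained control
#'
#' Background fluorescence is taken from an unstained control suspension of
#' equivalent age: the gate threshold is a high quantile (default 99.5th
#' percentile) of the control tdTomato intensities, and events strictly
#' above it are called germ.
#'
#' @param events data.frame with a `tdtomato` column.
#' @param control_events non-empty data.frame (or numeric vector) of
#'   unstained-control tdTomato intensities.
#' @param quantile_level control quantile defining the threshold.
#' @return list with `germ` (logical per event) and `threshold`.
#' @export
gate_tdtomato <- function(events, control_events, quantile_level = 0.995) {
  ctl <- if (is.data.frame(control_events)) control_events$tdtomato
         else control_events
  if (length(ctl) == 0) stop("empty unstained control")
  thr <- as.numeric(quantile(ctl, quantile_level, type = 7))
  list(germ = events$tdtomato > thr, threshold = thr)
}

#' Split eGFP+ germ events into Bright / Mid / Dim tertiles
#'
#' For each sample, the eGFP+ intensity range — from the positivity
#' threshold to the sample maximum — is divided into three equal-width bins
#' (on the log10 scale by default, since cytometry intensities span
#' decades), labelled Dim, Mid, Bright from low to high. Events below the
#' positivity threshold are eGFP−. Bins are closed on the left of the upper
#' bin: an event exactly at a cutpoint takes the higher bin.
#'
#' @param egfp numeric eGFP intensities of gated germ events (one sample).
#' @param positive_threshold intensity above which an event is eGFP+
#'   (events at or above it are positive).
#' @param scale `"log10"` or `"linear"`.
#' @return list of class `gate_result`: `labels` (factor with levels
#'   `eGFPneg`, `Dim`, `Mid`, `Bright`), `cutpoints` (the two internal
#'   boundaries on the intensity scale), `positive_threshold`, `scale`,
#'   `empty_tertiles` (character vector of tertiles with zero events).
#' @export
split_egfp_tertiles <- function(egfp, positive_threshold,
                                scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  stopifnot(positive_threshold > 0)
  pos <- egfp >= positive_threshold
  labels <- rep("eGFPneg", length(egfp))
  cutpoints <- c(NA_real_, NA_real_)
  if (any(pos)) {
    f <- if (scale == "log10") log10 else identity
    finv <- if (scale == "log10") function(x) 10^x else identity
    lo <- f(positive_threshold)
    hi <- f(max(egfp[pos]))
    cut1 <- lo + (hi - lo) / 3
    cut2 <- lo + 2 * (hi - lo) / 3
    x <- f(egfp[pos])
    labels[pos] <- ifelse(x >= cut2, "Bright",
                          ifelse(x >= cut1, "Mid", "Dim"))
    cutpoints <- finv(c(cut1, cut2))
  }
  labels <- factor(labels, levels = c("eGFPneg", "Dim", "Mid", "Bright"))
  empties <- setdiff(c("Dim", "Mid", "Bright"), as.character(unique(labels)))
  structure(list(labels = labels, cutpoints = cutpoints,
                 positive_threshold = positive_threshold, scale = scale,
                 empty_tertiles = if (any(pos)) empties
                                  else c("Dim", "Mid", "Bright")),
            class = "gate_result")
}

#' Cell-cycle fractions from univariate DNA content
#'
#' Locates the 2N (G0/G1) peak as the mode of a DNA-content histogram and
#' places the gate at 1.5 times the mode (i.e. 3N). Because S-phase cells
#' form a roughly uniform bridge between the 2N and 4N peaks, half of them
#' fall below that gate; the S/G2/M estimate therefore adds a bridge
#' correction equal to twice the mass observed between 1.25 and 1.5 times
#' the mode, which is exactly unbiased for a uniform bridge and adds
#' nothing when the bridge is empty. The raw above-gate fraction is also
#' returned.
#'
#' @param dna numeric DNA-content values.
#' @param min_events minimum events for a defined estimate (default 50).
#' @param n_bins histogram bins used to locate the 2N mode.
#' @return list: `g0g1`, `sgm` (bridge-corrected, complementary to `g0g1`),
#'   `sgm_above_threshold` (raw fraction above the gate), `mode_2n`,
#'   `threshold`, `defined`.
#' @export
cell_cycle_fractions <- function(dna, min_events = 50L, n_bins = 128L) {
  if (length(dna) < min_events) {
    return(list(g0g1 = NA_real_, sgm = NA_real_,
                sgm_above_threshold = NA_real_, mode_2n = NA_real_,
                threshold = NA_real_, defined = FALSE))
  }
  h <- graphics::hist(dna, breaks = n_bins, plot = FALSE)
  mode_2n <- h$mids[which.max(h$counts)]
  thr <- 1.5 * mode_2n
  above <- mean(dna > thr)
  bridge_window <- mean(dna > 1.25 * mode_2n & dna <= thr)
  sgm <- min(1, above + 2 * bridge_window)
  list(g0g1 = 1 - sgm, sgm = sgm, sgm_above_threshold = above,
       mode_2n = mode_2n, threshold = thr, defined = TRUE)
}

#' KIT+ incidence and its subset composition among germ events
#'
#' @param events data.frame of gated germ events with a `kit` column.
#' @param labels tertile labels for the same events (factor from
#'   [split_egfp_tertiles()]).
#' @param kit_threshold intensity above which an event is KIT+.
#' @return list: `kit_fraction` (share of germ events that are KIT+),
#'   `composition` (named proportions of KIT+ events across subset labels,
#'   summing to 1; NA-flagged when there are no KIT+ events), `n_kit_pos`.
#' @export
kit_composition <- function(events, labels, kit_threshold) {
  if (is.null(events$kit)) stop("KIT channel missing from events")
  stopifnot(length(labels) == nrow(events))
  kit_pos <- events$kit > kit_threshold
  frac <- mean(kit_pos)
  if (!any(kit_pos)) {
    return(list(kit_fraction = 0, composition = NULL, n_kit_pos = 0L))
  }
  comp <- table(labels[kit_pos]) / sum(kit_pos)
  list(kit_fraction = frac, composition = c(comp),
       n_kit_pos = sum(kit_pos))
}

#' Developmental-kinetics table: counts, fold changes and plateau calls
#'
#' For each subset across ordered ages: event counts, absolute cells per
#' animal (event count times a per-age conversion factor), percent of the
#' germline, fold change versus the previous age, and a plateau flag. The
#' plateau is called at the first age `i` such that the fold changes at
#' ages `i, ..., i + plateau_run - 1` all satisfy `|fold - 1| <=
#' plateau_tol`.
#'
#' @param counts matrix or data.frame of event counts, ages (ordered) in
#'   rows and subsets in columns.
#' @param cells_per_event named numeric per-age factors converting event
#'   counts to cells per animal (default 1).
#' @param plateau_tol tolerance on `|fold - 1|` (default 0.15).
#' @param plateau_run consecutive compliant intervals required (default 2).
#' @return data.frame with one row per age x subset: `age`, `subset`,
#'   `count`, `cells_per_animal`, `percent_of_germline`, `fold_change`
#'   (NA at the first age or over a zero previous count), `plateau`
#'   (TRUE exactly at the first age opening a compliant run, FALSE
#'   elsewhere; all-FALSE when no plateau is reached).
#' @export
kinetics_table <- function(counts, cells_per_event = NULL,
                           plateau_tol = 0.15, plateau_run = 2L) {
  counts <- as.matrix(counts)
  ages <- rownames(counts)
  if (is.null(ages)) ages <- as.character(seq_len(nrow(counts)))
  subsets <- colnames(counts)
  if (is.null(subsets)) subsets <- paste0("subset", seq_len(ncol(counts)))
  if (is.null(cells_per_event))
    cells_per_event <- setNames(rep(1, nrow(counts)), ages)
  germ_totals <- rowSums(counts)
  out <- list()
  for (s in seq_along(subsets)) {
    x <- counts[, s]
    fold <- c(NA_real_, ifelse(x[-length(x)] > 0,
                               x[-1] / x[-length(x)], NA_real_))
    ok <- !is.na(fold) & abs(fold - 1) <= plateau_tol
    plateau_age <- NA_integer_
    for (i in seq_along(x)) {
      run <- i:min(length(x), i + plateau_run - 1L)
      if (length(run) == plateau_run && all(ok[run])) {
        plateau_age <- i
        break
      }
    }
    out[[s]] <- data.frame(
      age = ages, subset = subsets[s], count = as.numeric(x),
      cells_per_animal = as.numeric(x) * cells_per_event[ages],
      percent_of_germline = 100 * x / germ_totals,
      fold_change = fold,
      plateau = if (is.na(plateau_age)) rep(FALSE, length(x))
                else seq_along(x) == plateau_age)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
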