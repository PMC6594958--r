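#' Configuration for the synthetic flow-cytometry event generator
#'
#' Emulates per-event cytometry tables of the developing germline: a
#' tdTomato lineage label separating germ from non-germ events, eGFP
#' reporter intensities in log-spread subset bands (Bright / Mid / Dim /
#' eGFP-negative), bimodal DNA content with a uniform S-phase bridge, and an
#' optional KIT channel.
#'
#' Default subset bands sit inside the equal log-thirds of the positive
#' range (decade 1–4), so band-separated subsets are recoverable exactly by
#' tertile gating. Default per-age Bright counts rise ~4-fold between the
#' 3rd and 4th postnatal day and then plateau, mirroring the burst of SSC
#' self-renewal that establishes the foundational pool.
#'
#' @param ages ordered character vector of age labels.
#' @param subset_counts named list (one entry per age) of named integer
#'   vectors with events for `Bright`, `Mid`, `Dim`, `eGFPneg`, `nongerm`.
#' @param egfp_bands named list of log10-intensity ranges for the three
#'   positive subsets plus `eGFPneg`.
#' @param tdtomato_germ,tdtomato_background log-normal (meanlog, sdlog) for
#'   germ-event tdTomato and for background (non-germ and unstained
#'   control).
#' @param dna_g1_mode 2N DNA-content peak position; the 4N peak sits at
#'   twice this value.
#' @param dna_cv coefficient of variation of the 2N and 4N Gaussian peaks.
#' @param sgm_fraction named list per age of named numeric vectors: fraction
#'   of each subset in S/G2/M.
#' @param s_share fraction of the S/G2/M compartment in S phase (uniform
#'   DNA-content bridge between the 2N and 4N peaks); the remainder sits at
#'   the 4N peak (G2/M).
#' @param kit_positive_fraction named numeric vector: probability that an
#'   event of each subset is KIT+ (high KIT intensity); may be NULL to omit
#'   the KIT channel. Defaults put roughly an eighth of the germline in the
#'   KIT+ (differentiating) compartment at proliferative ages, almost all
#'   of it Dim or eGFP-negative.
#' @param cells_per_event harvest/dilution metadata converting analysed
#'   event counts to absolute cells per animal.
#' @param n_control unstained-control events per age.
#' @return list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(
    ages = c("P0", "P1", "P2", "P3", "P4", "P5", "P6"),
    subset_counts = NULL,
    egfp_bands = list(Dim = c(1.0, 1.9), Mid = c(2.1, 2.9),
                      Bright = c(3.1, 4.0), eGFPneg = c(-0.5, 0.8)),
    tdtomato_germ = c(meanlog = log(1000), sdlog = 0.25),
    tdtomato_background = c(meanlog = log(3), sdlog = 0.4),
    dna_g1_mode = 100,
    dna_cv = 0.05,
    sgm_fraction = NULL,
    s_share = 0.5,
    kit_positive_fraction = c(Bright = 0.002, Mid = 0.03, Dim = 0.42,
                              eGFPneg = 0.48, nongerm = 0),
    cells_per_event = 19.2,
    n_control = 2000L) {
  stopifnot(length(ages) >= 1, dna_g1_mode > 0, dna_cv > 0,
            s_share >= 0, s_share <= 1, n_control > 0)
  if (is.null(subset_counts)) {
    bright <- c(150, 220, 300, 1263, 1310, 1280, 1300)
    mid <- c(150, 200, 260, 500, 800, 1100, 1400)
    dim_ <- c(100, 140, 180, 300, 500, 800, 1200)
    neg <- c(400, 380, 360, 350, 380, 420, 450)
    nong <- rep(1000, 7)
    subset_counts <- lapply(seq_along(ages), function(i)
      c(Bright = bright[i], Mid = mid[i], Dim = dim_[i],
        eGFPneg = neg[i], nongerm = nong[i]))
    names(subset_counts) <- ages
    subset_counts <- subset_counts[seq_along(ages)]
  }
  stopifnot(identical(sort(names(subset_counts)), sort(ages)))
  if (is.null(sgm_fraction)) {
    # quiescent before mitotic reactivation, proliferative afterwards
    sgm_fraction <- lapply(ages, function(a) {
      f <- if (a %in% c("P0", "P1", "P2", "E16.5", "E18.5")) 0.05 else 0.45
      c(Bright = f, Mid = f, Dim = f, eGFPneg = f, nongerm = 0.1)
    })
    names(sgm_fraction) <- ages
  }
  lapply(sgm_fraction, function(f) stopifnot(all(f >= 0), all(f <= 1)))
  b <- egfp_bands
  stopifnot(b$Bright[1] > b$Mid[2], b$Mid[1] > b$Dim[2],
            b$Dim[1] > b$eGFPneg[2])
  structure(list(ages = ages, subset_counts = subset_counts,
                 egfp_bands = egfp_bands, tdtomato_germ = tdtomato_germ,
                 tdtomato_background = tdtomato_background,
                 dna_g1_mode = dna_g1_mode, dna_cv = dna_cv,
                 sgm_fraction = sgm_fraction, s_share = s_share,
                 kit_positive_fraction = kit_positive_fraction,
                 cells_per_event = cells_per_event,
                 n_control = as.integer(n_control)),
            class = "flow_sim_config")
}

.sim_dna <- function(n, sgm, cfg) {
  g1 <- cfg$dna_g1_mode
  sgm_flag <- runif(n) < sgm
  s_flag <- sgm_flag & (runif(n) < cfg$s_share)
  x <- rnorm(n, g1, g1 * cfg$dna_cv)                      # 2N peak
  g2m <- sgm_flag & !s_flag
  x[g2m] <- rnorm(sum(g2m), 2 * g1, 2 * g1 * cfg$dna_cv)  # 4N peak
  x[s_flag] <- runif(sum(s_flag), g1, 2 * g1)             # uniform S bridge
  list(dna = pmax(x, 0), sgm = sgm_flag, s = s_flag)
}

#' Simulate per-event cytometry tables with ground truth
#'
#' Event counts per subset match the configuration exactly. Germ events draw
#' tdTomato from the germ distribution, non-germ events from background;
#' eGFP is log-uniform within each subset band; DNA content is bimodal with
#' a uniform S-phase bridge; KIT intensity (when configured) is high for
#' binomially sampled KIT+ events and low otherwise.
#'
#' @param config a [flow_sim_config()].
#' @param seed integer RNG seed.
#' @return list with `events` (data.frame: `age`, `tdtomato`, `egfp`, `dna`,
#'   optional `kit`), `truth` (per-event `subset`, `germ`, `sgm`, `s_phase`,
#'   `kit_pos`) and `controls` (unstained-control data.frame per age with
#'   `age`, `tdtomato`).
#' @export
simulate_flow_events <- function(config, seed) {
  stopifnot(inherits(config, "flow_sim_config"))
  if (length(config$ages) == 0) stop("empty age list")
  set.seed(as.integer(seed))
  cfg <- config
  has_kit <- !is.null(cfg$kit_positive_fraction)
  ev <- list(); tr <- list(); ctl <- list()
  for (age in cfg$ages) {
    counts <- cfg$subset_counts[[age]]
    for (subset in names(counts)) {
      n <- counts[[subset]]
      if (n == 0) next
      germ <- subset != "nongerm"
      td <- if (germ)
        rlnorm(n, cfg$tdtomato_germ[["meanlog"]], cfg$tdtomato_germ[["sdlog"]])
      else
        rlnorm(n, cfg$tdtomato_background[["meanlog"]],
               cfg$tdtomato_background[["sdlog"]])
      band <- if (germ && subset != "nongerm") cfg$egfp_bands[[subset]]
              else cfg$egfp_bands$eGFPneg
      eg <- 10^runif(n, band[1], band[2])
      cc <- .sim_dna(n, cfg$sgm_fraction[[age]][[subset]], cfg)
      kit_pos <- if (has_kit)
        runif(n) < cfg$kit_positive_fraction[[subset]] else rep(NA, n)
      kit <- if (has_kit)
        ifelse(kit_pos, rlnorm(n, log(500), 0.3), rlnorm(n, log(5), 0.4))
      else NULL
      e <- data.frame(age = age, tdtomato = td, egfp = eg, dna = cc$dna)
      if (has_kit) e$kit <- kit
      ev[[length(ev) + 1L]] <- e
      tr[[length(tr) + 1L]] <- data.frame(
        age = age, subset = subset, germ = germ, sgm = cc$sgm,
        s_phase = cc$s, kit_pos = kit_pos)
    }
    ctl[[age]] <- data.frame(
      age = age,
      tdtomato = rlnorm(cfg$n_control, cfg$tdtomato_background[["meanlog"]],
                        cfg$tdtomato_background[["sdlog"]]))
  }
  list(events = do.call(rbind, ev), truth = do.call(rbind, tr),
       controls = do.call(rbind, ctl))
}
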