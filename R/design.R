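#' Describe the two-diet partial-hepatectomy study design
#'
#' The design the generator emulates: rats pair-fed an ethanol (EtOH) or
#' carbohydrate-control (CHO) liquid diet, 70% partial hepatectomy at time 0,
#' livers sampled over a regeneration time course, with an anti-miR-21 (AM21)
#' locked-nucleic-acid arm and a saline arm at baseline and 24 h.
#'
#' @param diets diet labels.
#' @param times_h strictly increasing sampling times in hours; the first
#'   element is the baseline.
#' @param treatments treatment labels; the first is the untreated arm.
#' @param treatment_times_h hours at which treated (non-first-arm) samples
#'   exist; must be a subset of `times_h`.
#' @param n_reps biological replicates per design cell (>= 2).
#' @param panel_size number of miRNAs on the assay panel.
#' @return object of class `study_design`.
#' @export
study_design <- function(diets = c("CHO", "EtOH"),
                         times_h = c(0, 6, 24, 72),
                         treatments = c("untreated", "saline", "AM21"),
                         treatment_times_h = c(0, 24),
                         n_reps = 3,
                         panel_size = 420) {
  if (length(diets) == 0L) stop("empty field: diets")
  if (length(times_h) == 0L) stop("empty field: times_h")
  if (length(treatments) == 0L) stop("empty field: treatments")
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!all(treatment_times_h %in% times_h)) {
    stop("treatment_times_h must be a subset of times_h")
  }
  structure(list(diets = diets, times_h = times_h, treatments = treatments,
                 treatment_times_h = treatment_times_h, n_reps = n_reps,
                 panel_size = panel_size),
            class = "study_design")
}

#' Enumerate the sample table implied by a study design
#'
#' Untreated samples exist at every time point; treated arms (all but the
#' first treatment label) exist only at `treatment_times_h`.
#'
#' @param design a [study_design()].
#' @return sample metadata data frame (`sample_id`, `diet`, `time_h`,
#'   `treatment`, `replicate`).
#' @export
generate_design <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  for (diet in design$diets) {
    for (trt in design$treatments) {
      times <- if (trt == design$treatments[1]) design$times_h else design$treatment_times_h
      for (t in times) {
        r <- seq_len(design$n_reps)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_t%g_r%d", diet, trt, t, r),
          diet = diet, time_h = t, treatment = trt, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_sample_table(do.call(rbind, rows))
}

#' Configuration of the synthetic count generator
#'
#' Defaults encode the study conditions the generator emulates: a 420-miRNA
#' NanoString-style panel spanning several orders of magnitude in abundance,
#' negative-binomial counts (variance \eqn{\mu + \phi \mu^2}), fold-change
#' patterns planted to mirror the reported regeneration dynamics (25 miRNAs
#' upregulated and 6 downregulated at the later time points in EtOH, 10 of the
#' upregulated ones also transiently down at 6 h in CHO, plus 5
#' diet-independent responders — 36 differentially expressed in total), one
#' positively and four negatively miR-21-correlated miRNAs driven by a shared
#' latent factor, and a fixed log2 knockdown of miR-21 under AM21 that
#' propagates to the correlated partners through that factor.
#'
#' @param baseline_mean_log2,baseline_sd_log2 log-normal parameters (log2
#'   scale) of per-miRNA baseline abundance.
#' @param dispersion_phi negative-binomial dispersion (0 = Poisson),
#'   capturing technical extra-Poisson noise of the counting assay;
#'   animal-to-animal biological variation is modeled separately by
#'   `biological_sd_log2`, so the two noise layers are tunable independently.
#' @param library_size_range min/max total counts per sample.
#' @param planted_patterns list of planted trajectory entries, each a list
#'   with `mirna`, `delta` (per-step log2 effect size) and `pattern`, a named
#'   list mapping diet -> integer vector in \{-1, 0, 1\} per non-baseline time.
#' @param reference_mirna id of the miR-21 analog.
#' @param pos_corr_ids,neg_corr_ids miRNAs sharing the latent factor with the
#'   reference with positive / negative loading.
#' @param corr_strength latent-factor loading in (0, 1].
#' @param biological_sd_log2 per-miRNA biological log2 noise SD.
#' @param am21_knockdown_log2 log2 reduction of the reference miRNA under the
#'   AM21 arm (2 = four-fold knockdown).
#' @param seed integer seed governing all randomness of the generator.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(baseline_mean_log2 = 7,
                             baseline_sd_log2 = 2,
                             dispersion_phi = 0.01,
                             library_size_range = c(2e5, 1e6),
                             planted_patterns = default_planted_patterns(),
                             reference_mirna = "miR-21",
                             pos_corr_ids = "miR-340-5p",
                             neg_corr_ids = c("miR-365", "let-7a",
                                              "miR-1224", "miR-146a"),
                             corr_strength = 0.9,
                             biological_sd_log2 = 0.5,
                             am21_knockdown_log2 = 2,
                             seed = 1L) {
  stopifnot(dispersion_phi >= 0, corr_strength > 0, corr_strength <= 1,
            baseline_sd_log2 > 0, biological_sd_log2 >= 0,
            length(library_size_range) == 2, library_size_range[1] > 0,
            diff(library_size_range) >= 0)
  for (p in planted_patterns) {
    stopifnot(is.character(p$mirna), is.numeric(p$delta), is.finite(p$delta),
              is.list(p$pattern))
  }
  structure(list(baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 dispersion_phi = dispersion_phi,
                 library_size_range = library_size_range,
                 planted_patterns = planted_patterns,
                 reference_mirna = reference_mirna,
                 pos_corr_ids = pos_corr_ids,
                 neg_corr_ids = neg_corr_ids,
                 corr_strength = corr_strength,
                 biological_sd_log2 = biological_sd_log2,
                 am21_knockdown_log2 = am21_knockdown_log2,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default planted fold-change patterns
#'
#' Encodes the headline regeneration dynamics over the {6, 24, 72} h
#' post-hepatectomy trajectory (patterns are per non-baseline time):
#' \itemize{
#'   \item 25 miRNAs up at 24 and 72 h in EtOH only (`0UU`), among them the
#'     16-member stellate-cell activation signature including miR-21 and the
#'     positively correlated partner miR-340-5p; the first 10 of these are
#'     also transiently down at 6 h in CHO (`D00`);
#'   \item 6 miRNAs down at 24 and 72 h in EtOH only (`0DD`), among them the
#'     four negatively miR-21-correlated partners;
#'   \item 5 diet-independent responders up throughout (`UUU` in both diets).
#' }
#' In total 36 planted differentially expressed miRNAs by 72 h across the two
#' groups. Per-step effect `delta` defaults to 3 log2 units.
#'
#' @param delta per-step log2 effect magnitude.
#' @return list of planted-pattern entries (see [synthetic_config()]).
#' @export
default_planted_patterns <- function(delta = 3) {
  hsc_up <- c("let-7b", "let-7c", "let-7e", "miR-125b-5p", "miR-132",
              "miR-143", "miR-145", "miR-152", "miR-199a-5p", "miR-21",
              "miR-210", "miR-214", "miR-22", "miR-221", "miR-222", "miR-31")
  up_etoh <- c(hsc_up, "miR-340-5p",
               sprintf("miR-sim-up-%02d", 1:8))          # 25 total
  down_etoh <- c("miR-365", "let-7a", "miR-1224", "miR-146a",
                 sprintf("miR-sim-dn-%02d", 1:2))        # 6 total
  shared_up <- sprintf("miR-sim-sh-%02d", 1:5)           # 5 total
  pat <- function(mirna, cho, etoh) {
    list(mirna = mirna, delta = delta,
         pattern = list(CHO = cho, EtOH = etoh))
  }
  c(
    lapply(seq_along(up_etoh), function(i) {
      cho <- if (i <= 10) c(-1L, 0L, 0L) else c(0L, 0L, 0L)
      pat(up_etoh[i], cho, c(0L, 1L, 1L))
    }),
    lapply(down_etoh, pat, cho = c(0L, 0L, 0L), etoh = c(0L, -1L, -1L)),
    lapply(shared_up, pat, cho = c(1L, 1L, 1L), etoh = c(1L, 1L, 1L))
  )
}
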