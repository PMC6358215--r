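#' Catalog of laboratory cross designs
#'
#' The single-generation cross designs used to characterise drive
#' performance, as \code{\link{cross_design}} objects keyed by name:
#'
#' \describe{
#'   \item{D1_siteB_female / D1_siteB_male, D1_siteE_female / D1_siteE_male,
#'     D1_siteY_female}{synthetic-target-site drives homing into EGFP
#'     (autosomal sites B and E, both parental sexes; X-linked site Y,
#'     female parent only — males are hemizygous, so paternal conversion is
#'     undefined by construction): drive/EGFP heterozygote crossed to an
#'     EGFP homozygote.}
#'   \item{D2}{split drive: drive/+; Cas9/+ female crossed to a w1118 male.
#'     The mother deposits both Cas9 and gRNA, so embryo cutting is active.}
#'   \item{D3a / D3b}{the Mendelian-control split crosses in which Cas9 and
#'     the drive enter from different parents, so the mother deposits Cas9
#'     XOR gRNA and no embryo resistance can form. D3a: drive/+ female with
#'     no Cas9 x Cas9-homozygous male (gRNA deposited only). D3b:
#'     Cas9-homozygous female with no drive x hemizygous-drive male (Cas9
#'     deposited only).}
#'   \item{D4}{Cas9-carryover cross: a mosaic-yellow female that inherited
#'     the drive allele (dsRed) from her mother but no genomic Cas9 (no
#'     EGFP), and so was exposed to maternally deposited Cas9 and gRNA,
#'     crossed to a w1118 male. Her germline runs on carried-over Cas9.}
#'   \item{D5}{drive-heterozygous female whose drive allele came from her
#'     father (so she received maternally deposited Cas9 but no deposited
#'     gRNA; the genomic drive allele supplies gRNA), no genomic Cas9,
#'     crossed to a w1118 male.}
#'   \item{D6}{standard drive targeting the X-linked yellow gene:
#'     drive-heterozygous female x w1118 male.}
#'   \item{std_cinnabar_female / std_cinnabar_male, std_white_female}{the
#'     comparison standard drives targeting natural genes (autosomal
#'     cinnabar, both parental sexes; X-linked white, female only), modeled
#'     with the same recessive loss-of-function marker channel as yellow.}
#' }
#'
#' @return Named list of \code{\link{cross_design}} objects.
#' @examples
#' names(design_catalog())
#' @export
design_catalog <- function() {
  cfg_syn_auto <- drive_system_config("synthetic_target", "autosome", TRUE, "egfp_eye")
  cfg_syn_x <- drive_system_config("synthetic_target", "X", TRUE, "egfp_eye")
  cfg_split <- drive_system_config("split", "X", FALSE, "yellow_body")
  cfg_std_x <- drive_system_config("standard", "X", TRUE, "yellow_body")
  cfg_std_auto <- drive_system_config("standard", "autosome", TRUE, "yellow_body")

  het_f <- function() locus_genotype("female", c("DRIVE", "WILD"))
  het_m <- function() locus_genotype("male", c("DRIVE", "WILD"))
  wt_f <- function() locus_genotype("female", c("WILD", "WILD"))
  wt_m_auto <- function() locus_genotype("male", c("WILD", "WILD"))
  wt_m_x <- function() locus_genotype("male", "WILD")

  designs <- list(
    cross_design("D1_siteB_female", het_f(), wt_m_auto(), cfg_syn_auto),
    cross_design("D1_siteB_male", wt_f(), het_m(), cfg_syn_auto),
    cross_design("D1_siteE_female", het_f(), wt_m_auto(), cfg_syn_auto),
    cross_design("D1_siteE_male", wt_f(), het_m(), cfg_syn_auto),
    cross_design("D1_siteY_female", het_f(), wt_m_x(), cfg_syn_x),

    cross_design("D2",
                 locus_genotype("female", c("DRIVE", "WILD"), c("CAS9", "ABSENT")),
                 wt_m_x(), cfg_split),

    cross_design("D3a", het_f(),
                 locus_genotype("male", "WILD", c("CAS9", "CAS9")), cfg_split),
    cross_design("D3b",
                 locus_genotype("female", c("WILD", "WILD"), c("CAS9", "CAS9")),
                 locus_genotype("male", "DRIVE"), cfg_split),

    cross_design("D4",
                 locus_genotype("female", c("DRIVE", "WILD"),
                                mosaic = c("intact", "mosaic_cut")),
                 wt_m_x(), cfg_split,
                 mother_deposition_received = deposition_state(TRUE, TRUE)),

    cross_design("D5", het_f(), wt_m_x(), cfg_split,
                 mother_deposition_received = deposition_state(TRUE, FALSE)),

    cross_design("D6", het_f(), wt_m_x(), cfg_std_x),

    cross_design("std_cinnabar_female", het_f(), wt_m_auto(), cfg_std_auto),
    cross_design("std_cinnabar_male", wt_f(), het_m(), cfg_std_auto),
    cross_design("std_white_female", het_f(), wt_m_x(), cfg_std_x)
  )
  stats::setNames(designs, vapply(designs, function(d) d$name, character(1)))
}

estimator_by_name <- function(name) {
  switch(name,
         drive_inheritance_rate = drive_inheritance_rate,
         conversion_efficiency = conversion_efficiency,
         embryo_r2_rate_yellow = embryo_r2_rate_yellow,
         embryo_r2_rate_egfp = embryo_r2_rate_egfp,
         germline_r2_rate_sons = germline_r2_rate_sons,
         stop("unknown estimator: ", name))
}

#' Monte-Carlo parameter recovery for one design/estimator pair
#'
#' Simulates \code{replicates} independent pooled experiments of a design
#' under known true parameters, applies the estimator to each pooled count
#' table, and reports the mean recovered value with its empirical standard
#' error (SD of replicate estimates / sqrt(replicates)). Deterministic under
#' a fixed seed; replicate r runs with master seed mixed from
#' \code{(seed, r)}.
#'
#' @param design a \code{\link{cross_design}} or a name from
#'   \code{\link{design_catalog}}.
#' @param true_params \code{\link{drive_params}} used for simulation.
#' @param estimator estimator name (see \code{\link{conversion_efficiency}}
#'   and friends) or a function from count table to \code{drive_estimate}.
#' @param n_crosses,n_per_cross experiment scale per replicate (default
#'   40 crosses x 100 offspring, giving SEs comparable to the published
#'   uncertainty).
#' @param replicates number of independent replicate experiments.
#' @param seed integer master seed.
#' @param true_value the known truth for the recovered quantity, for the
#'   report (optional).
#' @return A one-row data.frame of class \code{recovery_report}: design,
#'   estimator, true value, mean estimate, empirical SE, replicates, seed;
#'   the per-replicate estimates are attached as attribute
#'   \code{"estimates"}.
#' @examples
#' run_recovery("D2", drive_params(c_f = 0.74, e_cut = 0),
#'              "conversion_efficiency", n_crosses = 5, n_per_cross = 50,
#'              replicates = 5, seed = 1, true_value = 0.74)
#' @export
run_recovery <- function(design, true_params, estimator,
                         n_crosses = 40, n_per_cross = 100,
                         replicates = 50, seed = 1, true_value = NA_real_) {
  if (is.character(design)) {
    cat_designs <- design_catalog()
    if (!design %in% names(cat_designs)) stop("unknown design: ", design)
    design <- cat_designs[[design]]
  }
  est_name <- if (is.character(estimator)) estimator else deparse(substitute(estimator))
  est_fun <- if (is.character(estimator)) estimator_by_name(estimator) else estimator
  stopifnot(replicates >= 1)
  ests <- vapply(seq_len(replicates), function(r) {
    t <- simulate_experiment(design, true_params, n_crosses, n_per_cross,
                             seed = mix_seed(seed, 70000 + r))
    est_fun(t)$point
  }, numeric(1))
  rep_df <- data.frame(design = design$name,
                       estimator = est_name,
                       true_value = true_value,
                       mean_estimate = mean(ests),
                       empirical_se = stats::sd(ests) / sqrt(replicates),
                       replicates = replicates,
                       seed = seed,
                       stringsAsFactors = FALSE)
  structure(rep_df, estimates = ests,
            class = c("recovery_report", "data.frame"))
}

#' Per-fly estimates across single-female crosses
#'
#' Simulates \code{n_flies} independent single-mother crosses and applies an
#' estimator to each fly's brood separately. Used to expose all-or-nothing
#' patterns such as Cas9 carryover, where most flies convert near
#' \code{c_carry} and a fraction \code{1 - p_active} show none.
#'
#' @param design a \code{\link{cross_design}} or catalog name.
#' @param params \code{\link{drive_params}}.
#' @param n_flies number of mothers.
#' @param n_per_fly offspring per mother.
#' @param estimator estimator name or function.
#' @param seed integer master seed.
#' @return Numeric vector of per-fly point estimates.
#' @export
per_fly_estimates <- function(design, params, n_flies, n_per_fly,
                              estimator = "conversion_efficiency", seed = 1) {
  if (is.character(design)) design <- design_catalog()[[design]]
  est_fun <- if (is.character(estimator)) estimator_by_name(estimator) else estimator
  res <- simulate_experiment(design, params, n_flies, n_per_fly, seed,
                             keep_crosses = TRUE)
  vapply(res$crosses, function(t) est_fun(t)$point, numeric(1))
}

#' Exact binomial check for Mendelian drive inheritance
#'
#' Tests the pooled dsRed fraction against the Mendelian expectation of 1/2
#' with an exact two-sided binomial test. Valid when exactly one parent
#' carries a single drive allele (heterozygous, or hemizygous at an X-linked
#' target — in the latter case all daughters and no sons are dsRed, so the
#' overall fraction is still Binomial(n, 1/2) under 1:1 sex ratio).
#'
#' @param t a \code{\link{count_table}}.
#' @param alpha significance level for the pass/fail verdict (default 0.01).
#' @return List with \code{pass} (TRUE when p >= alpha), \code{p_value},
#'   \code{dsred}, \code{n}.
#' @export
mendelian_check <- function(t, alpha = 0.01) {
  ct_check(t)
  n <- sum(t$count)
  if (n < 1) stop("mendelian_check: no offspring")
  k <- sum(t$count[t$dsred])
  p <- binom.test(k, n, p = 0.5)$p.value
  list(pass = p >= alpha, p_value = p, dsred = k, n = n)
}

#' Published drive-performance parameterisations
#'
#' The measured performance values of the seven characterised drives, as
#' simulation truths: male/female germline conversion efficiency and
#' early-embryo r2 resistance rate per drive, with the catalog designs used
#' to re-measure them. Germline resistance and mosaicism are set to zero
#' (not separately quantified for these crosses) and all resistance is r2.
#' Male conversion entries are absent for X-linked targets, where males are
#' hemizygous.
#'
#' @return Named list; each element has \code{params}
#'   (\code{\link{drive_params}}), design names \code{female_design},
#'   \code{male_design} (or NA), \code{embryo_design}, and
#'   \code{embryo_readout} (\code{"egfp"} or \code{"yellow"}).
#' @export
table1_params <- function() {
  entry <- function(c_m, c_f, e_cut, female_design, male_design, embryo_readout,
                    embryo_denominator = "all") {
    list(params = drive_params(c_f = c_f, c_m = if (is.na(c_m)) 0 else c_m,
                               r_f = 0, r_m = 0, r1_fraction = 0,
                               e_cut = e_cut, e_mosaic = 0),
         female_design = female_design, male_design = male_design,
         embryo_design = female_design, embryo_readout = embryo_readout,
         embryo_denominator = embryo_denominator)
  }
  list(
    "EGFP site B" = entry(0.32, 0.52, 0.88, "D1_siteB_female", "D1_siteB_male", "egfp"),
    "EGFP site E" = entry(0.46, 0.54, 0.91, "D1_siteE_female", "D1_siteE_male", "egfp"),
    "EGFP site Y" = entry(NA, 0.53, 0.80, "D1_siteY_female", NA_character_, "egfp",
                          embryo_denominator = "daughters"),
    "cinnabar" = entry(0.39, 0.54, 1.00, "std_cinnabar_female", "std_cinnabar_male", "yellow"),
    "white" = entry(NA, 0.59, 0.77, "std_white_female", NA_character_, "yellow"),
    "Split-yellow" = entry(NA, 0.74, 0.74, "D2", NA_character_, "yellow"),
    "yellow" = entry(NA, 0.63, 0.20, "D6", NA_character_, "yellow")
  )
}

#' Re-measure the drive performance table by simulation
#'
#' For every drive in \code{params_per_drive}, simulates the female-parent
#' conversion cross, the male-parent conversion cross (autosomal targets
#' only; X-linked entries stay empty by construction, since males are
#' hemizygous) and the embryo-resistance cross, then recovers male/female
#' conversion efficiency and the embryo r2 rate with the matching
#' estimators.
#'
#' @param params_per_drive named list as returned by
#'   \code{\link{table1_params}}.
#' @param seed integer master seed.
#' @param n_crosses,n_per_cross experiment scale per cell.
#' @return A data.frame with one row per drive: recovered
#'   \code{male_conversion}, \code{female_conversion}, \code{embryo_r2} and
#'   their binomial SEs (NA where undefined by construction).
#' @export
table1_reproduction <- function(params_per_drive = table1_params(), seed = 1,
                                n_crosses = 40, n_per_cross = 100) {
  designs <- design_catalog()
  cell <- function(design_name, params, est_fun, seed_off) {
    if (is.na(design_name)) return(c(NA_real_, NA_real_))
    t <- simulate_experiment(designs[[design_name]], params,
                             n_crosses, n_per_cross,
                             seed = mix_seed(seed, seed_off))
    e <- est_fun(t)
    c(e$point, e$se)
  }
  rows <- lapply(seq_along(params_per_drive), function(i) {
    spec <- params_per_drive[[i]]
    emb_fun <- if (spec$embryo_readout == "egfp") {
      function(t) embryo_r2_rate_egfp(t, denominator = spec$embryo_denominator)
    } else {
      embryo_r2_rate_yellow
    }
    male <- cell(spec$male_design, spec$params, conversion_efficiency, 3L * i)
    female <- cell(spec$female_design, spec$params, conversion_efficiency, 3L * i + 1L)
    embryo <- cell(spec$embryo_design, spec$params, emb_fun, 3L * i + 2L)
    data.frame(drive = names(params_per_drive)[i],
               male_conversion = male[1L], male_se = male[2L],
               female_conversion = female[1L], female_se = female[2L],
               embryo_r2 = embryo[1L], embryo_se = embryo[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
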