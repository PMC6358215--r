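## Per-cross substream seeds: Lehmer-style mix of (seed, index) mod 2^31 - 1.
## Multipliers kept small enough that double arithmetic stays exact (< 2^53),
## so the same (seed, index) pair always yields the same substream regardless
## of execution order.
mix_seed <- function(seed, index) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271 + as.numeric(index) * 16807 + 12345) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

#' A single-generation cross design
#'
#' Bundles the parental genotype templates, the drive-system configuration,
#' and the deposition state each parent itself received as an egg. The
#' parental deposition state is what powers Cas9-carryover germlines: a
#' parent with no genomic Cas9 but \code{cas9_deposited = TRUE} can convert
#' with the carryover parameters. It is one-generation memory only; it never
#' propagates to the grandoffspring.
#'
#' @param name identifier for the design.
#' @param mother,father \code{\link{locus_genotype}} templates (mother female,
#'   father male).
#' @param config a \code{\link{drive_system_config}}.
#' @param mother_deposition_received,father_deposition_received
#'   \code{\link{deposition_state}} the parent received as an egg (defaults:
#'   none).
#' @return An object of class \code{cross_design}.
#' @export
cross_design <- function(name, mother, father, config,
                         mother_deposition_received = deposition_state(),
                         father_deposition_received = deposition_state()) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(mother, "locus_genotype"), inherits(father, "locus_genotype"),
            inherits(config, "drive_system_config"),
            inherits(mother_deposition_received, "deposition_state"),
            inherits(father_deposition_received, "deposition_state"))
  if (mother$sex != "female") stop("cross_design: mother must be female")
  if (father$sex != "male") stop("cross_design: father must be male")
  validate_genotype(mother, config)
  validate_genotype(father, config)
  structure(list(name = name, mother = mother, father = father, config = config,
                 mother_deposition_received = mother_deposition_received,
                 father_deposition_received = father_deposition_received),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("<cross_design> %s (%s drive, %s-linked target)\n",
              x$name, x$config$system, x$config$target_linkage))
  cat("  mother: "); print(x$mother)
  cat("  father: "); print(x$father)
  if (x$mother_deposition_received$cas9_deposited ||
      x$mother_deposition_received$grna_deposited)
    cat(sprintf("  mother received: Cas9 %s, gRNA %s\n",
                x$mother_deposition_received$cas9_deposited,
                x$mother_deposition_received$grna_deposited))
  invisible(x)
}

## Resolve one individual's germline Cas9 activity and the (c, r) pair its
## gametogenesis uses. Germline homing/resistance requires a genomic gRNA
## source (a drive allele) plus Cas9 that is either genomic or carried over
## from maternal deposition. The carryover path is all-or-nothing per
## individual: active with probability p_active. One uniform is always drawn
## so the RNG call pattern does not depend on parameter values (keeps common
## random numbers comparable across parameter grids).
resolve_germline_activity <- function(parent, dep_received, params, config) {
  u <- runif(1)
  has_drive <- any(parent$target == "DRIVE")
  if (!has_drive) return(list(c = 0, r = 0, source = "none"))
  genomic_cas9 <- any(parent$support == "CAS9") ||
    (config$drive_carries_cas9 && has_drive)
  if (genomic_cas9) {
    if (parent$sex == "female") list(c = params$c_f, r = params$r_f, source = "genomic")
    else list(c = params$c_m, r = params$r_m, source = "genomic")
  } else if (dep_received$cas9_deposited && u < params$p_active) {
    list(c = params$c_carry, r = params$r_carry, source = "carryover")
  } else {
    list(c = 0, r = 0, source = "none")
  }
}

## Draw n gametes from one parent given resolved germline activity.
## Germline modification happens per gamete: in a DRIVE/WILD heterozygote
## with an active nuclease the WILD allele becomes DRIVE with probability c,
## a resistance allele with probability r (r1 with r1_fraction, else r2) and
## stays WILD otherwise; then one of the two (possibly modified) alleles is
## transmitted uniformly. Any other genotype segregates Mendelian: drive,
## r1 and r2 homologs are never cut (target site destroyed), and mosaic_cut
## alleles are germline-WILD. The support locus always segregates Mendelian.
## All four uniform vectors are drawn unconditionally (common-random-number
## stability).
draw_gametes <- function(parent, activity, params, n) {
  u_conv <- runif(n); u_kind <- runif(n); u_pick <- runif(n); u_sup <- runif(n)
  tg <- parent$target
  if (length(tg) == 2L && sum(tg == "DRIVE") == 1L && sum(tg == "WILD") == 1L) {
    drive_first <- tg[1L] == "DRIVE"
    wild_out <- ifelse(u_conv < activity$c, "DRIVE",
                ifelse(u_conv < activity$c + activity$r,
                       ifelse(u_kind < params$r1_fraction, "R1", "R2"),
                       "WILD"))
    a1 <- if (drive_first) rep("DRIVE", n) else wild_out
    a2 <- if (drive_first) wild_out else rep("DRIVE", n)
    target <- ifelse(u_pick < 0.5, a1, a2)
  } else if (length(tg) == 1L) {
    target <- rep(tg, n)
  } else {
    target <- ifelse(u_pick < 0.5, tg[1L], tg[2L])
  }
  support <- ifelse(u_sup < 0.5, parent$support[1L], parent$support[2L])
  list(target = target, support = support)
}

#' Draw gametes from one parent's germline
#'
#' Simulates gametogenesis for a single individual: resolves the germline
#' nuclease activity once for the individual (genomic Cas9 if present;
#' otherwise carried-over maternal Cas9, active with probability
#' \code{p_active}; otherwise none), then draws \code{n} gametes. In a
#' drive/wild heterozygote with an active germline nuclease the wild-type
#' allele is converted to a drive allele with probability \code{c}
#' (sex-specific, or \code{c_carry} under carryover), becomes a resistance
#' allele with probability \code{r}, and is transmitted alongside the drive
#' allele with equal probability. All other genotypes segregate Mendelian.
#'
#' Uses the current R RNG stream; call \code{set.seed()} for reproducibility.
#'
#' @param parent a \code{\link{locus_genotype}}.
#' @param parent_deposition_received \code{\link{deposition_state}} the parent
#'   received as an egg.
#' @param params \code{\link{drive_params}}.
#' @param config \code{\link{drive_system_config}}.
#' @param n number of gametes to draw.
#' @return A data.frame with columns \code{target} and \code{support}, one
#'   row per gamete.
#' @examples
#' set.seed(1)
#' cfg <- drive_system_config("standard", "X", TRUE, "yellow_body")
#' mom <- locus_genotype("female", c("DRIVE", "WILD"))
#' table(germline_transmit(mom, deposition_state(), drive_params(c_f = 0.6),
#'                         cfg, n = 1000)$target)
#' @export
germline_transmit <- function(parent, parent_deposition_received = deposition_state(),
                              params = drive_params(), config, n = 1) {
  validate_genotype(parent, config)
  stopifnot(inherits(params, "drive_params"), n >= 1)
  act <- resolve_germline_activity(parent, parent_deposition_received, params, config)
  g <- draw_gametes(parent, act, params, n)
  data.frame(target = g$target, support = g$support, stringsAsFactors = FALSE)
}

## Vectorised early-embryo modification. Applies only when the mother
## deposited BOTH Cas9 and gRNA; each WILD target allele is independently
## fully cut (resistance, flag full_cut) with probability e_cut, mosaically
## cut (flag mosaic_cut, state unchanged) with probability e_mosaic, else
## left intact. Drive/r1/r2 alleles are never modified, and embryo cutting
## never produces drive alleles (no homology-directed repair at this stage).
embryo_modify_frame <- function(off, mother_dep, params) {
  if (!(mother_dep$cas9_deposited && mother_dep$grna_deposited)) return(off)
  n <- nrow(off)
  for (side in c("m", "p")) {
    al <- off[[paste0("t", side)]]
    fl <- off[[paste0("f", side)]]
    u <- runif(n); uk <- runif(n)
    idx <- !is.na(al) & al == "WILD"
    full <- idx & u < params$e_cut
    mos <- idx & !full & u < params$e_cut + params$e_mosaic
    al[full] <- ifelse(uk[full] < params$r1_fraction, "R1", "R2")
    fl[full] <- "full_cut"
    fl[mos] <- "mosaic_cut"
    off[[paste0("t", side)]] <- al
    off[[paste0("f", side)]] <- fl
  }
  off
}

#' Early-embryo target modification of a zygote
#'
#' When the mother deposited both Cas9 and gRNA, each \code{WILD} target
#' allele of the freshly formed zygote is independently converted to a
#' resistance allele (r1 with probability \code{r1_fraction}, else r2) with
#' probability \code{e_cut}, or flagged \code{mosaic_cut} (state unchanged)
#' with probability \code{e_mosaic}. If either deposition is missing the
#' zygote is returned unmodified — both components must be maternally
#' deposited for embryo resistance alleles to form. Drive and resistance
#' alleles are never modified.
#'
#' @param zygote a \code{\link{locus_genotype}} with all flags
#'   \code{"intact"}.
#' @param mother_dep the \code{\link{deposition_state}} of the egg.
#' @param params \code{\link{drive_params}}.
#' @return The (possibly modified) \code{locus_genotype}.
#' @export
embryo_modify <- function(zygote, mother_dep, params = drive_params()) {
  stopifnot(inherits(zygote, "locus_genotype"),
            inherits(mother_dep, "deposition_state"),
            inherits(params, "drive_params"))
  two <- length(zygote$target) == 2L
  off <- data.frame(tm = zygote$target[1L],
                    tp = if (two) zygote$target[2L] else NA_character_,
                    fm = zygote$mosaic[1L],
                    fp = if (two) zygote$mosaic[2L] else NA_character_,
                    stringsAsFactors = FALSE)
  off <- embryo_modify_frame(off, mother_dep, params)
  target <- c(off$tm, if (two) off$tp)
  mosaic <- c(off$fm, if (two) off$fp)
  locus_genotype(zygote$sex, target, zygote$support, mosaic)
}

#' Simulate the offspring of one cross
#'
#' Composes gametogenesis, fertilisation, early-embryo modification and
#' phenotype scoring for \code{n_offspring} offspring of one mating pair.
#' Offspring sex is drawn 1:1. At an X-linked target, fathers transmit their
#' single target allele to daughters only; sons are hemizygous for the
#' maternal allele. The support locus is autosomal and segregates from both
#' parents. Each parent's germline Cas9 activity (including the carryover
#' all-or-nothing draw) is resolved once per call, i.e. once per individual
#' parent.
#'
#' Uses the current R RNG stream; \code{\link{simulate_experiment}} wraps
#' this with per-cross substreams for reproducible pooled experiments.
#'
#' @param design a \code{\link{cross_design}}.
#' @param params \code{\link{drive_params}}.
#' @param n_offspring number of offspring (>= 1).
#' @return A data.frame with one row per offspring: genotype columns
#'   (\code{tm}, \code{tp} maternal/paternal target allele, \code{fm},
#'   \code{fp} embryo flags, \code{s1}, \code{s2} support alleles) and
#'   phenotype columns (\code{sex}, \code{dsred}, \code{egfp}, \code{body}).
#' @examples
#' set.seed(7)
#' d <- design_catalog()[["D2"]]
#' head(simulate_cross(d, drive_params(c_f = 0.74), 10))
#' @export
simulate_cross <- function(design, params = drive_params(), n_offspring) {
  stopifnot(inherits(design, "cross_design"), inherits(params, "drive_params"),
            n_offspring >= 1)
  config <- design$config
  n <- as.integer(n_offspring)
  act_m <- resolve_germline_activity(design$mother, design$mother_deposition_received,
                                     params, config)
  act_f <- resolve_germline_activity(design$father, design$father_deposition_received,
                                     params, config)
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  gm <- draw_gametes(design$mother, act_m, params, n)
  gf <- draw_gametes(design$father, act_f, params, n)
  tp <- gf$target
  if (config$target_linkage == "X") tp[sex == "male"] <- NA_character_
  off <- data.frame(sex = sex,
                    tm = gm$target, tp = tp,
                    fm = rep("intact", n),
                    fp = ifelse(is.na(tp), NA_character_, "intact"),
                    s1 = gm$support, s2 = gf$support,
                    stringsAsFactors = FALSE)
  dep <- deposition_of_mother(design$mother, config)
  off <- embryo_modify_frame(off, dep, params)
  cbind(off, phenotype_frame(off, config))
}

## ---- count tables ----------------------------------------------------------

CT_COLS <- c("sex", "dsred", "egfp", "body", "count")

canonical_order <- function(df) {
  df[order(df$sex, df$dsred, df$egfp, df$body), , drop = FALSE]
}

#' Construct a phenotype count table
#'
#' A count table tallies offspring by the scored phenotype key
#' (sex, dsRed, EGFP class, body class); it is the sole input to the
#' estimators. Rows are stored in a canonical sort order so that identical
#' tallies compare identical.
#'
#' @param df data.frame with columns \code{sex}, \code{dsred} (logical),
#'   \code{egfp}, \code{body}, \code{count} (non-negative integers).
#' @param design design name the counts came from (metadata).
#' @param n_crosses number of crosses pooled (metadata).
#' @return An object of class \code{count_table} (a data.frame).
#' @export
count_table <- function(df, design = NA_character_, n_crosses = NA_integer_) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) {
    df <- data.frame(sex = character(), dsred = logical(), egfp = character(),
                     body = character(), count = integer(),
                     stringsAsFactors = FALSE)
  }
  if (!identical(names(df), CT_COLS))
    stop("count_table: columns must be exactly ", paste(CT_COLS, collapse = ", "))
  if (!all(df$sex %in% c("female", "male"))) stop("count_table: bad sex value")
  if (!is.logical(df$dsred) || anyNA(df$dsred)) stop("count_table: dsred must be TRUE/FALSE")
  if (!all(df$egfp %in% EGFP_CLASSES)) stop("count_table: bad egfp value")
  if (!all(df$body %in% BODY_CLASSES)) stop("count_table: bad body value")
  cnt <- df$count
  if (!is.numeric(cnt) || anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("count_table: counts must be non-negative integers")
  df$count <- as.integer(round(cnt))
  key <- paste(df$sex, df$dsred, df$egfp, df$body)
  if (anyDuplicated(key)) stop("count_table: duplicate phenotype key")
  df <- canonical_order(df)
  rownames(df) <- NULL
  structure(df, design = design, n_crosses = n_crosses,
            class = c("count_table", "data.frame"))
}

## Phenotype-key counts for one offspring frame (fast tally path).
key_counts <- function(off) {
  tab <- table(paste(off$sex, off$dsred, off$egfp, off$body, sep = "\t"))
  stats::setNames(as.integer(tab), names(tab))
}

keys_to_table <- function(kc, design = NA_character_, n_crosses = NA_integer_) {
  if (length(kc) == 0L) return(count_table(data.frame(), design, n_crosses))
  parts <- do.call(rbind, strsplit(names(kc), "\t", fixed = TRUE))
  df <- data.frame(sex = parts[, 1L], dsred = parts[, 2L] == "TRUE",
                   egfp = parts[, 3L], body = parts[, 4L],
                   count = as.integer(kc), stringsAsFactors = FALSE)
  count_table(df, design, n_crosses)
}

#' Tally simulated offspring into a count table
#'
#' @param off offspring data.frame from \code{\link{simulate_cross}}.
#' @param design design name (metadata).
#' @param n_crosses number of crosses pooled (metadata).
#' @return A \code{\link{count_table}}.
#' @export
tally_offspring <- function(off, design = NA_character_, n_crosses = 1L) {
  if (nrow(off) == 0L) return(count_table(data.frame(), design, n_crosses))
  keys_to_table(key_counts(off), design, n_crosses)
}

## Sum two tallies.
merge_tallies <- function(a, b) {
  both <- rbind(as.data.frame(a), as.data.frame(b))
  if (nrow(both) == 0L) return(count_table(data.frame()))
  agg <- aggregate(count ~ sex + dsred + egfp + body, data = both, FUN = sum)
  count_table(agg[, CT_COLS])
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> design: %s, crosses pooled: %s, total offspring: %d\n",
              attr(x, "design"), attr(x, "n_crosses"), sum(x$count)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Simulate a pooled multi-cross experiment
#'
#' Runs \code{n_crosses} independent crosses of the same design (each cross
#' gets its own mating pair, so per-individual randomness such as the
#' Cas9-carryover activity draw is refreshed per cross) and pools the
#' phenotype tallies, mirroring how laboratory vials are scored and summed.
#' Each cross runs in a deterministic RNG substream derived from
#' \code{(seed, cross index)}, so identical seeds give identical tables
#' regardless of execution order.
#'
#' @param design a \code{\link{cross_design}}.
#' @param params \code{\link{drive_params}}.
#' @param n_crosses number of independent crosses to pool (0 gives an empty
#'   table).
#' @param n_per_cross offspring per cross.
#' @param seed integer master seed.
#' @param keep_crosses if \code{TRUE}, also return the per-cross tallies
#'   (e.g. for jackknife uncertainty or per-fly estimates).
#' @return A \code{\link{count_table}}; with \code{keep_crosses = TRUE}, a
#'   list with elements \code{pooled} and \code{crosses}.
#' @examples
#' d <- design_catalog()[["D2"]]
#' simulate_experiment(d, drive_params(c_f = 0.74, e_cut = 0), 4, 25, seed = 1)
#' @export
simulate_experiment <- function(design, params = drive_params(),
                                n_crosses, n_per_cross, seed,
                                keep_crosses = FALSE) {
  stopifnot(n_crosses >= 0, n_per_cross >= 1, is.numeric(seed))
  acc <- integer()
  crosses <- vector("list", n_crosses)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  for (i in seq_len(n_crosses)) {
    set.seed(mix_seed(seed, i))
    kc <- key_counts(simulate_cross(design, params, n_per_cross))
    new <- setdiff(names(kc), names(acc))
    if (length(new)) acc[new] <- 0L
    acc[names(kc)] <- acc[names(kc)] + kc
    if (keep_crosses) crosses[[i]] <- keys_to_table(kc, design$name, 1L)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  pooled <- keys_to_table(acc, design$name, as.integer(n_crosses))
  if (keep_crosses) list(pooled = pooled, crosses = crosses) else pooled
}
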