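TARGET_STATES  <- c("WILD", "DRIVE", "R1", "R2")
SUPPORT_STATES <- c("CAS9", "ABSENT")
MOSAIC_FLAGS   <- c("intact", "mosaic_cut", "full_cut")
EGFP_CLASSES   <- c("full", "mosaic", "none", "not_applicable")
BODY_CLASSES   <- c("wild", "yellow", "mosaic_yellow")

#' Describe a drive system architecture
#'
#' A configuration ties together the drive architecture (standard homing
#' drive, split drive with an unlinked Cas9 supporting element, or a drive
#' homing into a synthetic EGFP target site), the chromosomal linkage of the
#' target locus, and the visible marker disrupted when the target gene loses
#' function.
#'
#' Constraints enforced: a standard drive carries its own Cas9
#' (\code{drive_carries_cas9 = TRUE}); a split drive never does; a
#' synthetic-target drive homes into EGFP, so its functional marker is the
#' EGFP eye phenotype. For drives targeting natural recessive loss-of-function
#' markers (\emph{yellow}, and by the same logic \emph{cinnabar} or
#' \emph{white}), \code{target_functional_marker = "yellow_body"} is used
#' generically: the \code{body} phenotype channel records the recessive
#' target-gene phenotype.
#'
#' @param system one of \code{"standard"}, \code{"split"},
#'   \code{"synthetic_target"}.
#' @param target_linkage \code{"X"} or \code{"autosome"}.
#' @param drive_carries_cas9 logical; does the driving element itself encode
#'   Cas9?
#' @param target_functional_marker \code{"yellow_body"}, \code{"egfp_eye"} or
#'   \code{"none"}.
#' @return An object of class \code{drive_system_config}.
#' @examples
#' drive_system_config("split", "X", FALSE, "yellow_body")
#' @export
drive_system_config <- function(system = c("standard", "split", "synthetic_target"),
                                target_linkage = c("X", "autosome"),
                                drive_carries_cas9 = NULL,
                                target_functional_marker = c("yellow_body", "egfp_eye", "none")) {
  system <- match.arg(system)
  target_linkage <- match.arg(target_linkage)
  target_functional_marker <- match.arg(target_functional_marker)
  if (is.null(drive_carries_cas9)) {
    drive_carries_cas9 <- system != "split"
  }
  stopifnot(is.logical(drive_carries_cas9), length(drive_carries_cas9) == 1L)
  if (system == "standard" && !drive_carries_cas9)
    stop("a standard drive must carry its own Cas9")
  if (system == "split" && drive_carries_cas9)
    stop("a split drive element does not carry Cas9")
  if (system == "synthetic_target" && target_functional_marker != "egfp_eye")
    stop("a synthetic-target drive homes into EGFP; target_functional_marker must be 'egfp_eye'")
  structure(list(system = system,
                 target_linkage = target_linkage,
                 drive_carries_cas9 = drive_carries_cas9,
                 target_functional_marker = target_functional_marker),
            class = "drive_system_config")
}

#' @export
print.drive_system_config <- function(x, ...) {
  cat(sprintf("<drive_system_config> %s drive, %s-linked target, marker = %s, drive carries Cas9: %s\n",
              x$system, x$target_linkage, x$target_functional_marker, x$drive_carries_cas9))
  invisible(x)
}

#' Per-individual genotype at the target and support loci
#'
#' Holds one fly's allele states at the drive target locus (X-linked or
#' autosomal; males are hemizygous at X-linked targets, so carry one target
#' allele) and at the autosomal Cas9 support locus, plus per-target-allele
#' flags recording early-embryo modification history: \code{"full_cut"} marks
#' an allele converted to a resistance allele in the embryo, while
#' \code{"mosaic_cut"} marks an allele cut in only part of the soma (its
#' germline state remains \code{"WILD"} but the fly shows a mosaic phenotype).
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param target character vector of target allele states, each one of
#'   \code{"WILD"}, \code{"DRIVE"}, \code{"R1"}, \code{"R2"}; length 2, or 1
#'   for a male hemizygous at an X-linked target.
#' @param support length-2 character vector of \code{"CAS9"}/\code{"ABSENT"}.
#' @param mosaic character vector of embryo-modification flags (one per target
#'   allele), each \code{"intact"}, \code{"mosaic_cut"} or \code{"full_cut"}.
#' @return An object of class \code{locus_genotype}.
#' @examples
#' locus_genotype("female", c("DRIVE", "WILD"), c("CAS9", "ABSENT"))
#' @export
locus_genotype <- function(sex = c("female", "male"),
                           target,
                           support = c("ABSENT", "ABSENT"),
                           mosaic = NULL) {
  sex <- match.arg(sex)
  target <- as.character(target)
  support <- as.character(support)
  if (!length(target) %in% 1:2 || !all(target %in% TARGET_STATES))
    stop("target must be 1 or 2 allele states from {WILD, DRIVE, R1, R2}")
  if (length(support) != 2L || !all(support %in% SUPPORT_STATES))
    stop("support must be 2 allele states from {CAS9, ABSENT}")
  if (is.null(mosaic)) mosaic <- rep("intact", length(target))
  mosaic <- as.character(mosaic)
  if (length(mosaic) != length(target) || !all(mosaic %in% MOSAIC_FLAGS))
    stop("mosaic flags must match target alleles and be intact/mosaic_cut/full_cut")
  if (any(mosaic == "mosaic_cut" & target != "WILD"))
    stop("mosaic_cut alleles retain state WILD")
  structure(list(sex = sex, target = target, support = support, mosaic = mosaic),
            class = "locus_genotype")
}

#' @export
print.locus_genotype <- function(x, ...) {
  flags <- ifelse(x$mosaic == "intact", "", paste0("(", x$mosaic, ")"))
  cat(sprintf("<locus_genotype> %s  target: %s  support: %s\n",
              x$sex, paste0(x$target, flags, collapse = "/"),
              paste(x$support, collapse = "/")))
  invisible(x)
}

#' Check a genotype against a drive-system configuration
#'
#' Verifies the allele-list length matches sex and target linkage (males
#' hemizygous at X-linked targets carry one target allele, all other cases
#' two).
#'
#' @param g a \code{\link{locus_genotype}}.
#' @param config a \code{\link{drive_system_config}}.
#' @return \code{g}, invisibly; errors on mismatch.
#' @export
validate_genotype <- function(g, config) {
  stopifnot(inherits(g, "locus_genotype"), inherits(config, "drive_system_config"))
  expected <- if (config$target_linkage == "X" && g$sex == "male") 1L else 2L
  if (length(g$target) != expected)
    stop(sprintf("genotype/config mismatch: %s at %s-linked target must carry %d target allele(s)",
                 g$sex, config$target_linkage, expected))
  invisible(g)
}

#' Maternal deposition state of an egg
#'
#' Records whether an egg received maternally deposited Cas9 protein and/or
#' gRNA. Deposition is derived from the mother's own genotype only
#' (one-generation memory): maternally deposited Cas9 that the mother herself
#' received does not get re-deposited into her eggs.
#'
#' @param cas9_deposited,grna_deposited logicals.
#' @return An object of class \code{deposition_state}.
#' @export
deposition_state <- function(cas9_deposited = FALSE, grna_deposited = FALSE) {
  stopifnot(is.logical(cas9_deposited), is.logical(grna_deposited),
            length(cas9_deposited) == 1L, length(grna_deposited) == 1L,
            !is.na(cas9_deposited), !is.na(grna_deposited))
  structure(list(cas9_deposited = cas9_deposited, grna_deposited = grna_deposited),
            class = "deposition_state")
}

#' @export
print.deposition_state <- function(x, ...) {
  cat(sprintf("<deposition_state> Cas9: %s, gRNA: %s\n",
              x$cas9_deposited, x$grna_deposited))
  invisible(x)
}

#' Deposition an egg receives from its mother
#'
#' gRNA is deposited iff the mother carries at least one drive allele (the
#' drive element encodes the gRNA); Cas9 is deposited iff the mother carries a
#' genomic Cas9 source — a \code{CAS9} support allele, or any drive allele in
#' an architecture where the driving element carries Cas9.
#'
#' @param mother a female \code{\link{locus_genotype}}.
#' @param config the \code{\link{drive_system_config}}.
#' @return A \code{\link{deposition_state}}.
#' @examples
#' cfg <- drive_system_config("split", "X", FALSE, "yellow_body")
#' m <- locus_genotype("female", c("DRIVE", "WILD"))
#' deposition_of_mother(m, cfg)   # gRNA only: no genomic Cas9
#' @export
deposition_of_mother <- function(mother, config) {
  stopifnot(inherits(mother, "locus_genotype"), inherits(config, "drive_system_config"))
  if (mother$sex != "female")
    stop("deposition_of_mother: mother must be female")
  has_drive <- any(mother$target == "DRIVE")
  has_cas9 <- any(mother$support == "CAS9") || (config$drive_carries_cas9 && has_drive)
  deposition_state(cas9_deposited = has_cas9, grna_deposited = has_drive)
}

#' Number of functional target alleles
#'
#' Counts target alleles whose gene product is functional: \code{WILD} and
#' \code{r1} resistance alleles. \code{DRIVE} and \code{r2} alleles disrupt
#' the target gene.
#'
#' @param g a \code{\link{locus_genotype}}.
#' @return Integer count (0, 1 or 2).
#' @export
functional_target_count <- function(g) {
  stopifnot(inherits(g, "locus_genotype"))
  sum(g$target %in% c("WILD", "R1"))
}

## Vectorised phenotype core. `tm`/`tp` are maternal/paternal target allele
## states (tp NA for sons hemizygous at an X-linked target), `fm`/`fp` the
## matching embryo flags, `s1`/`s2` the support alleles.
phenotype_frame <- function(off, config) {
  tp_ok <- !is.na(off$tp)
  dsred <- off$tm == "DRIVE" | (tp_ok & off$tp == "DRIVE")
  func_m <- off$tm %in% c("WILD", "R1")
  func_p <- tp_ok & off$tp %in% c("WILD", "R1")
  nfunc <- func_m + func_p
  mosaic_any <- (func_m & off$fm == "mosaic_cut") |
    (func_p & !is.na(off$fp) & off$fp == "mosaic_cut")

  egfp <- rep("not_applicable", nrow(off))
  if (config$system == "synthetic_target") {
    egfp <- ifelse(nfunc == 0, "none", ifelse(mosaic_any, "mosaic", "full"))
  } else if (config$system == "split") {
    # the split supporting element is EGFP-marked: eye EGFP reports Cas9 carriage
    egfp <- ifelse(off$s1 == "CAS9" | off$s2 == "CAS9", "full", "none")
  }

  body <- rep("wild", nrow(off))
  if (config$target_functional_marker == "yellow_body") {
    body <- ifelse(nfunc == 0, "yellow", ifelse(mosaic_any, "mosaic_yellow", "wild"))
  }
  data.frame(dsred = dsred, egfp = egfp, body = body, stringsAsFactors = FALSE)
}

#' Observable phenotype of a genotype
#'
#' Maps a genotype to its scored marker phenotypes, deterministically:
#' \itemize{
#'   \item \code{dsred} is \code{TRUE} iff at least one drive allele is
#'     present (the dsRed marker travels with the driving element).
#'   \item For a synthetic-target drive, eye EGFP is \code{"full"} when at
#'     least one functional target allele is intact, \code{"mosaic"} when a
#'     functional allele carries a \code{mosaic_cut} embryo flag, and
#'     \code{"none"} when no functional target allele remains. For a split
#'     drive, eye EGFP reports carriage of the EGFP-marked Cas9 supporting
#'     element instead. For a standard drive it is \code{"not_applicable"}.
#'   \item When the target disrupts a recessive body/eye-colour marker
#'     (\code{"yellow_body"}), the body phenotype is \code{"yellow"} iff zero
#'     functional target alleles remain (recessive; males hemizygous), and
#'     \code{"mosaic_yellow"} when a \code{mosaic_cut} flag is present with at
#'     least one functional allele.
#' }
#' Mosaic classes are emitted post-classification: the microscope-level
#' scoring rule (mosaic = under 50\% EGFP eye coverage in drive carriers) is
#' assumed already applied.
#'
#' @param g a \code{\link{locus_genotype}}.
#' @param config the \code{\link{drive_system_config}}.
#' @return A list of class \code{phenotype_record} with fields \code{sex},
#'   \code{dsred}, \code{egfp}, \code{body}.
#' @examples
#' cfg <- drive_system_config("split", "X", FALSE, "yellow_body")
#' phenotype_of(locus_genotype("female", c("DRIVE", "R2")), cfg)
#' @export
phenotype_of <- function(g, config) {
  validate_genotype(g, config)
  tp <- if (length(g$target) == 2L) g$target[2L] else NA_character_
  fp <- if (length(g$target) == 2L) g$mosaic[2L] else NA_character_
  off <- data.frame(tm = g$target[1L], tp = tp,
                    fm = g$mosaic[1L], fp = fp,
                    s1 = g$support[1L], s2 = g$support[2L],
                    stringsAsFactors = FALSE)
  ph <- phenotype_frame(off, config)
  structure(list(sex = g$sex, dsred = ph$dsred, egfp = ph$egfp, body = ph$body),
            class = "phenotype_record")
}

#' @export
print.phenotype_record <- function(x, ...) {
  cat(sprintf("<phenotype_record> %s  dsRed: %s  EGFP: %s  body: %s\n",
              x$sex, x$dsred, x$egfp, x$body))
  invisible(x)
}
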