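#' Drive performance parameters of the inheritance model
#'
#' All probabilities of the homing-drive inheritance model. Defaults are the
#' measured values for the split drive targeting the X-linked \emph{yellow}
#' gene, the system characterised in most mechanistic detail; every field is
#' a probability in [0, 1].
#'
#' @param c_f,c_m probability that the single \code{WILD} target allele of a
#'   drive/wild heterozygous germline is converted to \code{DRIVE} (homing by
#'   homology-directed repair), in females / males. For X-linked targets
#'   males are hemizygous and never heterozygous, so \code{c_m} is inert.
#' @param r_f,r_m probability that the same allele instead becomes a germline
#'   resistance allele (end-joining repair). \code{c + r <= 1} per sex.
#' @param r1_fraction probability a newly formed resistance allele preserves
#'   target-gene function (r1) rather than disrupting it (r2). Not quantified
#'   experimentally; defaults to 0 so all resistance is r2.
#' @param e_cut probability a functional non-drive target allele in the
#'   zygote is fully cut and converted to a resistance allele in the early
#'   embryo, given that both Cas9 and gRNA were maternally deposited.
#' @param e_mosaic probability the allele is instead cut in only part of the
#'   soma (mosaic phenotype, germline state unchanged). \code{e_cut +
#'   e_mosaic <= 1}.
#' @param p_active probability that an individual with no genomic Cas9 but
#'   maternally deposited Cas9 retains germline-active carried-over Cas9 at
#'   all (the carryover effect is close to all-or-nothing per fly; 15 of 16
#'   carryover-exposed flies showed conversion, hence the default 15/16).
#' @param c_carry,r_carry conversion and germline-resistance probabilities
#'   under carried-over Cas9, replacing \code{c}/\code{r} when no genomic
#'   Cas9 source is present. \code{c_carry + r_carry <= 1}.
#' @return An object of class \code{drive_params}.
#' @examples
#' drive_params(c_f = 0.74, e_cut = 0.74)
#' @export
drive_params <- function(c_f = 0.74, c_m = 0,
                         r_f = 0, r_m = 0,
                         r1_fraction = 0,
                         e_cut = 0.74, e_mosaic = 0,
                         p_active = 15 / 16,
                         c_carry = 0.54, r_carry = 0.12) {
  p <- list(c_f = c_f, c_m = c_m, r_f = r_f, r_m = r_m,
            r1_fraction = r1_fraction, e_cut = e_cut, e_mosaic = e_mosaic,
            p_active = p_active, c_carry = c_carry, r_carry = r_carry)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("drive_params: %s must be a probability in [0, 1]", nm))
  }
  if (p$c_f + p$r_f > 1) stop("drive_params: c_f + r_f must not exceed 1")
  if (p$c_m + p$r_m > 1) stop("drive_params: c_m + r_m must not exceed 1")
  if (p$e_cut + p$e_mosaic > 1) stop("drive_params: e_cut + e_mosaic must not exceed 1")
  if (p$c_carry + p$r_carry > 1) stop("drive_params: c_carry + r_carry must not exceed 1")
  structure(p, class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params>\n")
  cat(sprintf("  germline conversion   c_f = %.3f, c_m = %.3f\n", x$c_f, x$c_m))
  cat(sprintf("  germline resistance   r_f = %.3f, r_m = %.3f (r1 fraction %.3f)\n",
              x$r_f, x$r_m, x$r1_fraction))
  cat(sprintf("  embryo cutting        e_cut = %.3f, e_mosaic = %.3f\n",
              x$e_cut, x$e_mosaic))
  cat(sprintf("  Cas9 carryover        p_active = %.3f, c_carry = %.3f, r_carry = %.3f\n",
              x$p_active, x$c_carry, x$r_carry))
  invisible(x)
}

#' Update a subset of drive parameters
#'
#' @param params a \code{\link{drive_params}} object.
#' @param ... named fields to replace.
#' @return A revalidated \code{drive_params} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "drive_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown drive parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  do.call(drive_params, p)
}
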