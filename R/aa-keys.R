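#' Amino acid categories of the factorial demand model
#'
#' The model works with 16 amino acid categories: nine indispensable (IAA)
#' groups -- histidine, isoleucine, leucine, lysine, the sulfur amino acids
#' (SAA = methionine + cysteine), the aromatic amino acids
#' (AAA = phenylalanine + tyrosine), threonine, tryptophan and valine -- and
#' seven dispensable (DAA) groups -- alanine, arginine, Asx
#' (aspartate + asparagine), Glx (glutamate + glutamine), glycine, proline and
#' serine. The composite categories (SAA, AAA, Asx, Glx) are never decomposed.
#'
#' @return A data frame with columns `aa` (category code) and `class`
#'   (`"IAA"` or `"DAA"`), one row per category, in conventional table order.
#' @examples
#' aa_keys()
#' @export
aa_keys <- function() {
  data.frame(
    aa = c(
      "His", "Ile", "Leu", "Lys", "SAA", "AAA", "Thr", "Trp", "Val",
      "Ala", "Arg", "Asx", "Glx", "Gly", "Pro", "Ser"
    ),
    class = rep(c("IAA", "DAA"), c(9L, 7L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname aa_keys
#' @export
iaa_codes <- function() aa_keys()$aa[aa_keys()$class == "IAA"]

#' @rdname aa_keys
#' @export
daa_codes <- function() aa_keys()$aa[aa_keys()$class == "DAA"]

#' Map an amino acid name to its model category
#'
#' Individual amino acids belonging to a composite category are folded into
#' it before any aggregation: Met/Cys -> SAA, Phe/Tyr -> AAA, Asp/Asn -> Asx,
#' Glu/Gln -> Glx. Codes that already name one of the 16 categories are
#' returned unchanged.
#'
#' @param aa Character vector of amino acid codes (three-letter).
#' @return Character vector of category codes.
#' @examples
#' canonical_aa(c("Met", "Gln", "Gly"))
#' @export
canonical_aa <- function(aa) {
  fold <- c(
    Met = "SAA", Cys = "SAA", Phe = "AAA", Tyr = "AAA",
    Asp = "Asx", Asn = "Asx", Glu = "Glx", Gln = "Glx"
  )
  out <- ifelse(aa %in% names(fold), unname(fold[aa]), aa)
  bad <- setdiff(unique(out), aa_keys()$aa)
  if (length(bad) > 0L) {
    stop("unknown amino acid code(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Average molar masses of the free amino acids
#'
#' Built-in table of average molecular weights (g/mol) of the free amino
#' acids, used for mol-to-mass conversion of urinary metabolite and
#' creatinine-normalised excretion records. Composite categories are not
#' listed; records carry the individual parent amino acid and are folded with
#' [canonical_aa()] after conversion.
#'
#' @param aa Optional character vector of codes to look up.
#' @return Named numeric vector of molar masses (g/mol).
#' @examples
#' aa_molar_mass("Trp")
#' @export
aa_molar_mass <- function(aa = NULL) {
  mm <- c(
    Ala = 89.09, Arg = 174.20, Asn = 132.12, Asp = 133.10, Cys = 121.16,
    Gln = 146.15, Glu = 147.13, Gly = 75.07, His = 155.15, Ile = 131.17,
    Leu = 131.17, Lys = 146.19, Met = 149.21, Phe = 165.19, Pro = 115.13,
    Ser = 105.09, Thr = 119.12, Trp = 204.23, Tyr = 181.19, Val = 117.15
  )
  if (is.null(aa)) {
    return(mm)
  }
  miss <- setdiff(aa, names(mm))
  if (length(miss) > 0L) {
    stop("no molar mass for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  mm[aa]
}

# internal: check a named per-AA vector covers all 16 categories
check_aa_cover <- function(x, what = "value") {
  missing <- setdiff(aa_keys()$aa, names(x))
  if (length(missing) > 0L) {
    stop(
      what, " missing for amino acid(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x[aa_keys()$aa]
}

# internal: half-up rounding used at the reporting layer so that printed
# tables match the convention of the source data (round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
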