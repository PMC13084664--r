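#' Convert a nitrogen mass to protein
#'
#' @param n_mass Nitrogen mass (mg N).
#' @param factor Nitrogen-to-protein conversion factor; default 6.25.
#' @return Protein mass (mg).
#' @examples
#' n_to_protein(5) # 31.25
#' @export
n_to_protein <- function(n_mass, factor = 6.25) {
  if (any(n_mass < 0)) stop("n_mass must be non-negative", call. = FALSE)
  factor * n_mass
}

#' Hair, skin, nail and miscellaneous losses per amino acid
#'
#' The total integumental-plus-miscellaneous nitrogen loss (default
#' 5 +/- 0.9 mg N/kgBW/d) is split into a miscellaneous component (1.8 mg
#' N/kgBW/d) apportioned by the amino acid composition of whole-body protein,
#' and a dermal (hair, skin, nail) component (the remainder, 3.2) apportioned
#' by the composition of hair/skin/nail protein. Each nitrogen part is
#' converted to protein with the 6.25 factor and multiplied by the relevant
#' composition (mg AA per g protein):
#'
#' `HSNM(aa) = 6.25 * misc_n * body(aa)/1000 + 6.25 * dermal_n * dermal(aa)/1000`
#'
#' Both loss parts scale with the nitrogen total, so the per-amino-acid SD is
#' taken proportional: `sd = mean * total_n_sd / total_n`.
#'
#' @param nitrogen List (or `nitrogen_loss_spec()`) with `total_n`,
#'   `miscellaneous_n` and `total_n_sd` in mg N/kgBW/d.
#' @param body,dermal Composition tables: either a named numeric vector
#'   (mg AA per g protein) or a data frame with columns `aa` and `mg_per_g`.
#'   Amino acids absent from a table contribute 0, with a warning.
#' @param constants A [model_constants()] object (supplies the 6.25 factor).
#' @return Data frame with columns `aa`, `mean`, `sd` (mg/kgBW/d) over all
#'   16 categories.
#' @export
derive_hsnm <- function(nitrogen = nitrogen_loss_spec(), body, dermal,
                        constants = model_constants()) {
  nitrogen <- nitrogen_loss_spec(
    total_n = nitrogen$total_n,
    miscellaneous_n = nitrogen$miscellaneous_n,
    total_n_sd = nitrogen$total_n_sd
  )
  body <- as_composition(body, "body")
  dermal <- as_composition(dermal, "dermal")
  dermal_n <- nitrogen$total_n - nitrogen$miscellaneous_n
  f <- constants$n_to_protein
  mean_val <- f * nitrogen$miscellaneous_n * body / 1000 +
    f * dermal_n * dermal / 1000
  data.frame(
    aa = aa_keys()$aa,
    mean = unname(mean_val),
    sd = unname(mean_val * nitrogen$total_n_sd / nitrogen$total_n),
    row.names = NULL
  )
}

#' @rdname derive_hsnm
#' @param total_n,miscellaneous_n,total_n_sd Nitrogen totals, mg N/kgBW/d.
#' @export
nitrogen_loss_spec <- function(total_n = 5, miscellaneous_n = 1.8,
                               total_n_sd = 0.9) {
  stopifnot(total_n > 0, miscellaneous_n >= 0, total_n_sd >= 0)
  if (total_n - miscellaneous_n <= 0) {
    stop("dermal nitrogen (total_n - miscellaneous_n) must be positive",
      call. = FALSE
    )
  }
  list(
    total_n = total_n, miscellaneous_n = miscellaneous_n,
    dermal_n = total_n - miscellaneous_n, total_n_sd = total_n_sd
  )
}

# internal: coerce a composition table to a full named vector over 16 keys
as_composition <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("aa", "mg_per_g") %in% names(x))) {
      stop(what, " composition needs columns aa, mg_per_g", call. = FALSE)
    }
    v <- stats::setNames(x$mg_per_g, canonical_aa(x$aa))
    v <- tapply(v, names(v), sum)[unique(names(v))]
  } else if (is.numeric(x) && !is.null(names(x))) {
    v <- stats::setNames(as.numeric(x), canonical_aa(names(x)))
  } else {
    stop(what, " composition must be a named vector or data frame",
      call. = FALSE
    )
  }
  if (any(v < 0)) stop(what, " composition must be non-negative", call. = FALSE)
  missing <- setdiff(aa_keys()$aa, names(v))
  if (length(missing) > 0L) {
    warning(
      what, " composition missing ", paste(missing, collapse = ", "),
      "; treated as 0"
    )
  }
  out <- stats::setNames(rep(0, 16L), aa_keys()$aa)
  out[names(v)[names(v) %in% aa_keys()$aa]] <-
    v[names(v) %in% aa_keys()$aa]
  out
}

#' Subject-number-weighted urinary free amino acid loss
#'
#' Combines urinary excretion study records for one amino acid. Each record's
#' daily excretion (mg/d) is divided by the study's subject body weight to
#' give mg/kgBW/d, then the mean and SD are combined across studies weighted
#' by subject number.
#'
#' @param records Data frame with columns `aa`, `mean` (mg/d), `sd` (mg/d),
#'   `n_subjects`, `body_weight` (kg); all rows must share one amino acid.
#' @return List with `mean` and `sd` in mg/kgBW/d.
#' @examples
#' weighted_ufaap(data.frame(
#'   aa = "His", mean = c(75, 150), sd = c(10, 10),
#'   n_subjects = c(5, 5), body_weight = 75
#' ))$mean # 1.5
#' @export
weighted_ufaap <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  need <- c("aa", "mean", "sd", "n_subjects", "body_weight")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(unique(records$aa)) != 1L) {
    stop("all records must refer to the same amino acid", call. = FALSE)
  }
  stopifnot(
    all(records$mean >= 0), all(records$sd >= 0),
    all(records$n_subjects >= 1), all(records$body_weight > 0)
  )
  v <- records$mean / records$body_weight
  s <- records$sd / records$body_weight
  w <- records$n_subjects
  list(
    mean = sum(w * v) / sum(w),
    sd = sum(w * s) / sum(w)
  )
}

#' Convert a creatinine-normalised urinary value to a mass loss
#'
#' Reference-range urinary data are often reported as mmol of analyte per mol
#' of creatinine. With a creatinine excretion of `creatinine_excretion`
#' mmol/kgBW/d the analyte loss is
#' `(value / 1000) * creatinine_excretion * molar_mass` mg/kgBW/d.
#'
#' @param value Excretion in mmol analyte per mol creatinine.
#' @param molar_mass Analyte molar mass, g/mol.
#' @param constants A [model_constants()] object.
#' @return Loss in mg/kgBW/d.
#' @examples
#' creatinine_normalized_to_mass(50, 100) # 1.0
#' @export
creatinine_normalized_to_mass <- function(value, molar_mass,
                                          constants = model_constants()) {
  if (any(value < 0)) stop("value must be non-negative", call. = FALSE)
  if (any(molar_mass <= 0)) stop("molar_mass must be positive", call. = FALSE)
  (value / 1000) * constants$creatinine_excretion * molar_mass
}

#' Amino acid loss implied by a urinary metabolite excretion
#'
#' Irreversible modification and functional conversion losses are estimated
#' from the urinary excretion of the end metabolite, assuming a fixed
#' stoichiometry (default mol-to-mol) with the parent amino acid. A
#' mol-per-day excretion converts as
#' `excretion * stoichiometry * molar_mass * 1000 / body_weight`
#' (mol/d -> mg/kgBW/d); creatinine-normalised records are converted with
#' [creatinine_normalized_to_mass()] semantics (already per kgBW).
#'
#' @param excretion Metabolite excretion, in mol/d or mmol/mol creatinine.
#' @param aa_molar_mass Parent amino acid molar mass, g/mol.
#' @param body_weight Subject body weight, kg (mol/d records only).
#' @param stoichiometry Mol of amino acid lost per mol metabolite.
#' @param unit `"mol_per_day"` or `"mmol_per_mol_creatinine"`.
#' @param constants A [model_constants()] object.
#' @return Loss in mg/kgBW/d.
#' @examples
#' metabolite_to_aa_loss(10e-6, aa_molar_mass("Trp"), body_weight = 75)
#' @export
metabolite_to_aa_loss <- function(excretion, aa_molar_mass, body_weight = 75,
                                  stoichiometry = 1, unit = "mol_per_day",
                                  constants = model_constants()) {
  unit <- match.arg(unit, c("mol_per_day", "mmol_per_mol_creatinine"))
  if (any(excretion < 0)) stop("excretion must be non-negative", call. = FALSE)
  if (any(stoichiometry <= 0)) {
    stop("stoichiometry must be positive", call. = FALSE)
  }
  out <- if (unit == "mol_per_day") {
    excretion * stoichiometry * aa_molar_mass * 1000 / body_weight
  } else {
    stoichiometry *
      creatinine_normalized_to_mass(excretion, aa_molar_mass, constants)
  }
  unname(out)
}

#' Assemble other losses (OL) per amino acid from metabolite records
#'
#' Converts each metabolite excretion record to a parent-amino-acid loss with
#' [metabolite_to_aa_loss()], folds individual parents into their composite
#' category ([canonical_aa()]), and sums within category. SDs are converted
#' the same way and combined by root-sum-of-squares. Categories with no
#' records get a loss of 0 (the em-dash cells of the source table).
#'
#' @param records Data frame with columns `metabolite`, `parent_aa`,
#'   `excretion`, `excretion_sd`, `unit`
#'   (`mol_per_day`/`mmol_per_mol_creatinine`), `stoichiometry`.
#' @param constants A [model_constants()] object (body weight, creatinine).
#' @return Data frame with columns `aa`, `mean`, `sd` over all 16 categories.
#' @export
assemble_ol <- function(records, constants = model_constants()) {
  need <- c(
    "metabolite", "parent_aa", "excretion", "excretion_sd", "unit",
    "stoichiometry"
  )
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  key <- canonical_aa(records$parent_aa) # errors on unknown parent
  mm <- aa_molar_mass(records$parent_aa)
  conv <- function(x) {
    vapply(seq_along(x), function(i) {
      metabolite_to_aa_loss(
        x[i], mm[i],
        body_weight = constants$body_weight,
        stoichiometry = records$stoichiometry[i],
        unit = records$unit[i], constants = constants
      )
    }, numeric(1))
  }
  loss <- conv(records$excretion)
  loss_sd <- conv(records$excretion_sd)
  out <- data.frame(
    aa = aa_keys()$aa, mean = 0, sd = 0, row.names = NULL
  )
  for (a in unique(key)) {
    i <- which(out$aa == a)
    out$mean[i] <- sum(loss[key == a])
    out$sd[i] <- propagate_sd(loss_sd[key == a])
  }
  out
}

#' Weighted urinary free amino acid and peptide losses per category
#'
#' Applies [weighted_ufaap()] per individual amino acid, converting
#' creatinine-normalised records first, then folds members into composite
#' categories (means add, SDs combine by root-sum-of-squares).
#'
#' @param records Data frame with columns `aa`, `unit` (`mg_per_day` or
#'   `mmol_per_mol_creatinine`), `mean`, `sd`, `n_subjects`, `body_weight`.
#' @param constants A [model_constants()] object.
#' @return Data frame with columns `aa`, `mean`, `sd` over all 16 categories.
#' @export
derive_ufaap <- function(records, constants = model_constants()) {
  need <- c("aa", "unit", "mean", "sd", "n_subjects", "body_weight")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  # convert creatinine-normalised rows to mg/d so one weighting path serves
  is_cr <- records$unit == "mmol_per_mol_creatinine"
  if (any(is_cr)) {
    mm <- aa_molar_mass(records$aa[is_cr])
    records$mean[is_cr] <- creatinine_normalized_to_mass(
      records$mean[is_cr], mm, constants
    ) * records$body_weight[is_cr]
    records$sd[is_cr] <- creatinine_normalized_to_mass(
      records$sd[is_cr], mm, constants
    ) * records$body_weight[is_cr]
  }
  key <- canonical_aa(records$aa)
  out <- data.frame(aa = aa_keys()$aa, mean = 0, sd = 0, row.names = NULL)
  for (a in unique(key)) {
    members <- unique(records$aa[key == a])
    m <- vapply(members, function(b) {
      unlist(weighted_ufaap(records[records$aa == b, , drop = FALSE]))
    }, numeric(2))
    i <- which(out$aa == a)
    out$mean[i] <- sum(m["mean", ])
    out$sd[i] <- propagate_sd(m["sd", ])
  }
  out
}
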