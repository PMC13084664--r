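#' Build a protein-quality scoring pattern
#'
#' A scoring pattern expresses each indispensable amino acid requirement (or
#' demand) as mg per g of the total protein requirement:
#' `pattern(aa) = demand(aa) / protein_demand` with the demand in mg/kgBW/d
#' and the protein requirement in g/kgBW/d. No rounding is applied here;
#' reporting rounds patterns to integers.
#'
#' @param per_aa_demand Named numeric vector over the nine IAA categories,
#'   mg/kgBW/d.
#' @param protein_demand Total protein requirement, g/kgBW/d (e.g. 0.66 for
#'   the FAO/WHO adult requirement).
#' @param label Pattern label (`"MMD"`, `"FAO"` or free text).
#' @return An object of class `scoring_pattern`: list with `label`, `values`
#'   (mg/g over the nine IAAs) and `protein_requirement` (g/kgBW/d).
#' @examples
#' build_pattern(c(
#'   His = 10, Ile = 20, Leu = 39, Lys = 30, SAA = 15,
#'   AAA = 25, Thr = 15, Trp = 4, Val = 26
#' ), 0.66, label = "FAO")
#' @export
build_pattern <- function(per_aa_demand, protein_demand, label = "custom") {
  if (protein_demand <= 0) {
    stop("protein_demand must be positive", call. = FALSE)
  }
  miss <- setdiff(iaa_codes(), names(per_aa_demand))
  if (length(miss) > 0L) {
    stop("demand missing IAA(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  values <- per_aa_demand[iaa_codes()] / protein_demand
  if (any(values <= 0)) {
    stop("pattern values must be positive for all nine IAAs", call. = FALSE)
  }
  structure(
    list(
      label = label, values = values,
      protein_requirement = protein_demand
    ),
    class = "scoring_pattern"
  )
}

#' Scoring pattern from a solved demand fit
#'
#' Divides the solved per-IAA demands by the solved total-protein demand
#' (converted to g/kgBW/d), giving the demand-based scoring pattern at full
#' precision.
#'
#' @param fit An `mmd_fit` from [solve_mmd_table()].
#' @return A `scoring_pattern` labelled `"MMD"`.
#' @export
mmd_pattern <- function(fit) {
  stopifnot(inherits(fit, "mmd_fit"))
  per <- fit$per_aa
  demand <- stats::setNames(per$mmd_mean, per$aa)[iaa_codes()]
  prot <- fit$totals$mean[fit$totals$group == "total_protein"] / 1000
  build_pattern(demand, prot, label = "MMD")
}

#' Define a dietary protein source
#'
#' A source is described either by its raw amino acid composition plus true
#' ileal digestibility (TID) values, or by precomputed digestible reference
#' ratios per scoring pattern (the regression form). TID resolution order for
#' each IAA: a per-amino-acid value, else the mean of the available
#' per-amino-acid values, else the total-protein TID, else the total-nitrogen
#' TID; if none resolves, scoring fails naming the amino acid. Tryptophan
#' composition must be present in the composition table; there is no silent
#' external fallback.
#'
#' @param name Source name.
#' @param composition Named numeric vector, mg IAA per g protein.
#' @param tid Named numeric vector of per-IAA TID fractions in 0..1 (may
#'   cover only some IAAs).
#' @param tid_protein,tid_total_n Optional scalar proxy TIDs.
#' @param reference_ratios Optional named list of named ratio vectors, one
#'   per pattern label (e.g. `list(MMD = c(His = 0.77, ...))`).
#' @return An object of class `protein_source`.
#' @export
protein_source <- function(name, composition = NULL, tid = NULL,
                           tid_protein = NULL, tid_total_n = NULL,
                           reference_ratios = NULL) {
  if (is.null(composition) && is.null(reference_ratios)) {
    stop("a protein source needs a composition or reference ratios",
      call. = FALSE
    )
  }
  if (!is.null(composition)) {
    miss <- setdiff(iaa_codes(), names(composition))
    if (length(miss) > 0L) {
      stop(
        "composition missing IAA(s): ", paste(miss, collapse = ", "),
        if ("Trp" %in% miss) " (tryptophan must be supplied, not looked up)",
        call. = FALSE
      )
    }
    if (any(composition < 0)) {
      stop("composition must be non-negative", call. = FALSE)
    }
  }
  if (!is.null(tid) && (any(tid < 0) || any(tid > 1))) {
    stop("tid values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      name = name, composition = composition, tid = tid,
      tid_protein = tid_protein, tid_total_n = tid_total_n,
      reference_ratios = reference_ratios
    ),
    class = "protein_source"
  )
}

#' Digestible indispensable amino acid content of a source
#'
#' Multiplies the composition of each IAA by its resolved true ileal
#' digestibility (see [protein_source()] for the resolution order).
#'
#' @param source A `protein_source` with a composition.
#' @return Named numeric vector, mg digestible IAA per g protein.
#' @export
digestible_content <- function(source) {
  stopifnot(inherits(source, "protein_source"))
  if (is.null(source$composition)) {
    stop("source '", source$name, "' has no composition table", call. = FALSE)
  }
  tid_mean <- if (!is.null(source$tid) && length(source$tid) > 0L) {
    mean(source$tid)
  } else {
    NULL
  }
  resolve <- function(aa) {
    if (!is.null(source$tid) && aa %in% names(source$tid)) {
      return(source$tid[[aa]])
    }
    for (v in list(tid_mean, source$tid_protein, source$tid_total_n)) {
      if (!is.null(v)) return(v)
    }
    stop("configuration error: no TID resolvable for ", aa, " in source '",
      source$name, "'",
      call. = FALSE
    )
  }
  vapply(
    stats::setNames(iaa_codes(), iaa_codes()),
    function(aa) source$composition[[aa]] * resolve(aa), numeric(1)
  )
}

#' Score a protein source against a scoring pattern (DIAAS)
#'
#' The reference ratio of each IAA is its digestible content divided by the
#' pattern value; the DIAAS is the minimum ratio, the limiting amino acids
#' are all IAAs attaining it (ties reported), and the required intake is the
#' pattern's protein requirement divided by the DIAAS. The score is *not*
#' truncated at 1.
#'
#' @param source A `protein_source`. If it carries precomputed
#'   `reference_ratios` for the pattern's label those are used directly;
#'   otherwise ratios are computed from composition and TID.
#' @param pattern A `scoring_pattern`.
#' @param tie_tol Ratios within this of the minimum count as limiting.
#' @return An object of class `diaas_result`: list with `source`, `pattern`,
#'   `reference_ratios`, `diaas`, `limiting`, `required_intake`.
#' @export
score_source <- function(source, pattern, tie_tol = 1e-9) {
  stopifnot(inherits(source, "protein_source"), inherits(pattern, "scoring_pattern"))
  ratios <- if (!is.null(source$reference_ratios) &&
    pattern$label %in% names(source$reference_ratios)) {
    rr <- source$reference_ratios[[pattern$label]]
    miss <- setdiff(iaa_codes(), names(rr))
    if (length(miss) > 0L) {
      stop("reference ratios missing IAA(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    rr[iaa_codes()]
  } else {
    digestible_content(source) / pattern$values
  }
  diaas <- min(ratios)
  structure(
    list(
      source = source$name,
      pattern = pattern$label,
      reference_ratios = ratios,
      diaas = diaas,
      limiting = names(ratios)[ratios <= diaas + tie_tol],
      required_intake = required_intake(pattern$protein_requirement, diaas)
    ),
    class = "diaas_result"
  )
}

#' Protein intake required to satisfy the demand through a given source
#'
#' @param protein_requirement Total protein demand or requirement, g/kgBW/d.
#' @param diaas Protein quality score of the source (untruncated).
#' @return Required intake, g/kgBW/d, satisfying
#'   `required_intake * diaas = protein_requirement`.
#' @examples
#' required_intake(0.66, 1.28) # 0.5156
#' @export
required_intake <- function(protein_requirement, diaas) {
  if (any(diaas <= 0)) stop("diaas must be positive", call. = FALSE)
  if (any(protein_requirement <= 0)) {
    stop("protein_requirement must be positive", call. = FALSE)
  }
  protein_requirement / diaas
}

#' Compare limiting amino acids under two scoring patterns
#'
#' @param source A `protein_source`.
#' @param pattern_a,pattern_b Two `scoring_pattern`s.
#' @return List with the two `diaas_result`s, the limiting sets and a
#'   `shifted` flag (TRUE when the limiting sets differ).
#' @export
limiting_shift <- function(source, pattern_a, pattern_b) {
  a <- score_source(source, pattern_a)
  b <- score_source(source, pattern_b)
  list(
    source = source$name,
    score_a = a, score_b = b,
    limiting_a = a$limiting, limiting_b = b$limiting,
    shifted = !setequal(a$limiting, b$limiting)
  )
}

#' Protein sources from a reference-ratio table
#'
#' Turns the pack's `reference_ratios` data frame (columns `source`,
#' `pattern`, `aa`, `ratio`) into a named list of [protein_source()]s in
#' precomputed-ratio form.
#'
#' @param ratios Reference-ratio data frame (e.g. from [load_pack()]).
#' @return Named list of `protein_source` objects.
#' @export
sources_from_ratios <- function(ratios) {
  stopifnot(all(c("source", "pattern", "aa", "ratio") %in% names(ratios)))
  out <- lapply(unique(ratios$source), function(s) {
    sub <- ratios[ratios$source == s, , drop = FALSE]
    rr <- lapply(split(sub, sub$pattern), function(d) {
      stats::setNames(d$ratio, d$aa)
    })
    protein_source(name = s, reference_ratios = rr)
  })
  stats::setNames(out, unique(ratios$source))
}

#' @export
print.scoring_pattern <- function(x, ...) {
  cat(sprintf(
    "Scoring pattern '%s' (protein requirement %.3f g/kgBW/d)\n",
    x$label, x$protein_requirement
  ))
  print(round(x$values, 1))
  invisible(x)
}

#' @export
print.diaas_result <- function(x, ...) {
  cat(sprintf(
    "%s vs %s pattern: DIAAS %.2f (limiting: %s), required intake %.2f g/kgBW/d\n",
    x$source, x$pattern, x$diaas, paste(x$limiting, collapse = ", "),
    x$required_intake
  ))
  invisible(x)
}
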