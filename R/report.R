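#' Formatted demand table (per amino acid with totals)
#'
#' Renders a solved fit as the conventional "mean (SD)" table at one decimal
#' place: one row per amino acid, totals rows per class, and a total-protein
#' row in which HSNM is taken at its aggregate nitrogen value (see
#' [solve_mmd_table()]). Formatting happens only here; the fit itself is kept
#' at full precision.
#'
#' @param fit An `mmd_fit`.
#' @return Data frame of formatted strings with columns `aa`, `io`,
#'   `pto_pp`, `pto_pa`, `egl`, `ufaap`, `hsnm`, `ol`, `mmd`.
#' @export
report_table_mmd <- function(fit) {
  stopifnot(inherits(fit, "mmd_fit"))
  per <- fit$per_aa
  nm <- loss_component_names()
  cell <- function(m, s) {
    ifelse(is.na(s),
      sprintf("%.1f", round_half_up(m, 1)),
      sprintf("%.1f (%.1f)", round_half_up(m, 1), round_half_up(s, 1))
    )
  }
  row_for <- function(label, means, sds) {
    out <- data.frame(aa = label, stringsAsFactors = FALSE)
    for (j in seq_along(means)) {
      out[[c("io", nm, "mmd")[j]]] <- cell(means[j], sds[j])
    }
    out
  }
  rows <- lapply(seq_len(nrow(per)), function(i) {
    row_for(
      per$aa[i],
      c(per$io_mean[i], unlist(per[i, paste0(nm, "_mean")]), per$mmd_mean[i]),
      c(per$io_sd[i], unlist(per[i, paste0(nm, "_sd")]), per$mmd_sd[i])
    )
  })
  class_row <- function(label, keep) {
    means <- c(
      sum(per$io_mean[keep]),
      vapply(nm, function(cn) sum(per[[paste0(cn, "_mean")]][keep]), numeric(1)),
      sum(per$mmd_mean[keep])
    )
    sds <- c(
      propagate_sd(per$io_sd[keep]),
      vapply(nm, function(cn) propagate_sd(per[[paste0(cn, "_sd")]][keep]), numeric(1)),
      propagate_sd(per$mmd_sd[keep])
    )
    row_for(label, means, sds)
  }
  # total-protein row: HSNM at its aggregate value, MMD/IO re-solved with it
  keep <- rep(TRUE, nrow(per))
  prot <- class_row("total_protein", keep)
  hsnm_agg <- fit$protein_alt$mmd_mean * (1 - fit$constants$io_rate) -
    sum(vapply(
      setdiff(nm, "hsnm"),
      function(cn) sum(per[[paste0(cn, "_mean")]]), numeric(1)
    ))
  prot$hsnm <- cell(hsnm_agg, propagate_sd(per$hsnm_sd))
  prot$mmd <- cell(fit$protein_alt$mmd_mean, propagate_sd(per$mmd_sd))
  prot$io <- cell(fit$protein_alt$io_mean, propagate_sd(per$io_sd))

  out <- do.call(rbind, c(
    rows,
    list(
      class_row("total_iaa", per$class == "IAA"),
      class_row("total_daa", per$class == "DAA"),
      prot
    )
  ))
  rownames(out) <- NULL
  out
}

#' Demand vs requirement comparison table
#'
#' Mirrors the published comparison of the solved demand against the FAO/WHO
#' adult requirements and the composition of body protein: integer demand
#' columns (mg/kgBW/d, half-up rounding), scoring patterns derived from the
#' integer demand columns (mg/g, the convention of the published table),
#' the body-protein composition column, and the IAA:DAA percentage split.
#'
#' @param fit An `mmd_fit`.
#' @param pack An `aa_pack` supplying the FAO/WHO requirement column and the
#'   body-protein composition.
#' @return List with `table` (data frame over the nine IAAs plus totals) and
#'   `iaa_daa` (named character vector of "IAA:DAA" strings per column).
#' @export
report_comparison <- function(fit, pack) {
  stopifnot(inherits(fit, "mmd_fit"), inherits(pack, "aa_pack"))
  req <- pack$requirements
  per <- fit$per_aa
  iaa <- iaa_codes()
  mmd_int <- round_half_up(stats::setNames(per$mmd_mean, per$aa)[iaa])
  prot_mmd <- round_half_up(
    fit$totals$mean[fit$totals$group == "total_protein"]
  )
  fao <- stats::setNames(req$fao_requirement, req$aa)
  body <- stats::setNames(req$body_protein, req$aa)
  prot_fao <- fao[["total_protein"]]
  tab <- data.frame(
    aa = iaa,
    mmd_demand = unname(mmd_int),
    fao_requirement = unname(fao[iaa]),
    mmd_pattern = unname(round_half_up(mmd_int / (prot_mmd / 1000))),
    fao_pattern = unname(round_half_up(fao[iaa] / (prot_fao / 1000))),
    body_protein = unname(body[iaa])
  )
  tot <- data.frame(
    aa = c("total_iaa", "total_protein"),
    mmd_demand = c(sum(tab$mmd_demand), prot_mmd),
    fao_requirement = c(sum(tab$fao_requirement), prot_fao),
    mmd_pattern = c(
      round_half_up(sum(tab$mmd_demand) / (prot_mmd / 1000)), 1000
    ),
    fao_pattern = c(
      round_half_up(sum(tab$fao_requirement) / (prot_fao / 1000)), 1000
    ),
    body_protein = c(sum(body[iaa]), 1000)
  )
  share <- function(iaa_total, prot_total) {
    p <- round_half_up(100 * iaa_total / prot_total)
    sprintf("%d:%d", p, 100 - p)
  }
  list(
    table = rbind(tab, tot),
    iaa_daa = c(
      mmd = share(
        fit$totals$mean[fit$totals$group == "total_iaa"],
        fit$totals$mean[fit$totals$group == "total_protein"]
      ),
      fao = share(sum(fao[iaa]), prot_fao),
      body = share(sum(body[iaa]), 1000)
    )
  )
}

#' Scoring patterns from a parameter pack's requirement table
#'
#' Builds the demand-based and FAO/WHO scoring patterns from the integer
#' demand/requirement columns of the pack (the published derivation), with
#' protein requirements in g/kgBW/d.
#'
#' @param pack An `aa_pack`.
#' @return List of two `scoring_pattern`s named `MMD` and `FAO`.
#' @export
pack_patterns <- function(pack) {
  req <- pack$requirements
  dem <- stats::setNames(req$mmd_demand, req$aa)
  fao <- stats::setNames(req$fao_requirement, req$aa)
  list(
    MMD = build_pattern(
      dem[iaa_codes()], dem[["total_protein"]] / 1000,
      label = "MMD"
    ),
    FAO = build_pattern(
      fao[iaa_codes()], fao[["total_protein"]] / 1000,
      label = "FAO"
    )
  )
}

#' Protein-quality report over the packaged sources
#'
#' Scores every protein source in the pack against both scoring patterns and
#' tabulates the reference ratios (2 dp), the DIAAS (minimum taken before
#' rounding), the limiting amino acids and the required protein intake.
#'
#' @param pack An `aa_pack`.
#' @param patterns Optional list of `scoring_pattern`s; default
#'   [pack_patterns()].
#' @return List with `ratios` (wide data frame of 2-dp reference ratios) and
#'   `scores` (data frame `source`, `pattern`, `diaas`, `limiting`,
#'   `required_intake`).
#' @export
report_diaas <- function(pack, patterns = pack_patterns(pack)) {
  sources <- sources_from_ratios(pack$reference_ratios)
  combos <- expand.grid(
    source = names(sources), pattern = names(patterns),
    stringsAsFactors = FALSE
  )
  scored <- lapply(seq_len(nrow(combos)), function(i) {
    score_source(sources[[combos$source[i]]], patterns[[combos$pattern[i]]])
  })
  ratios <- data.frame(aa = iaa_codes())
  for (s in scored) {
    ratios[[paste(s$source, s$pattern, sep = ".")]] <-
      round_half_up(unname(s$reference_ratios[iaa_codes()]), 2)
  }
  scores <- do.call(rbind, lapply(scored, function(s) {
    data.frame(
      source = s$source, pattern = s$pattern,
      diaas = s$diaas,
      limiting = paste(s$limiting, collapse = "+"),
      required_intake = s$required_intake
    )
  }))
  list(ratios = ratios, scores = scores)
}
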