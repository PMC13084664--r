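#' @keywords internal
"_PACKAGE"

# the six non-IO obligatory-loss components, in table order
loss_component_names <- function() {
  c("pto_pp", "pto_pa", "egl", "ufaap", "hsnm", "ol")
}

#' Solve the factorial demand equation for one amino acid
#'
#' The minimum metabolic demand (MMD) of an amino acid is the sum of its
#' obligatory losses: turnover-associated oxidation in the postprandial and
#' postabsorptive states (PTO_PP, PTO_PA), gut endogenous losses (EGL),
#' urinary free amino acids and peptides (UFAAP), hair/skin/nail and
#' miscellaneous losses (HSNM), other losses (OL), and the inevitable
#' oxidation (IO) of the absorbed intake itself. Because IO is a fixed
#' fraction `r` of the absorbed amount -- which at maintenance equals the MMD
#' -- the demand solves the fixed point `MMD = S + r * MMD`, i.e.
#' `MMD = S / (1 - r)` where `S` is the sum of the six non-IO components,
#' and then `IO = r * MMD`.
#'
#' Standard deviations are propagated by root-sum-of-squares over the seven
#' loss terms. When a directly estimated IO standard deviation is supplied via
#' `io_sd` it is used as the IO term; otherwise the IO term is derived from
#' the non-IO uncertainties as `r * rss(sds) / (1 - r)`.
#'
#' @param components Numeric vector of the six non-IO component means
#'   (mg/kgBW/d), named `pto_pp`, `pto_pa`, `egl`, `ufaap`, `hsnm`, `ol`
#'   (an unnamed length-6 vector is taken in that order).
#' @param constants A [model_constants()] object.
#' @param sds Optional numeric vector of the six component standard
#'   deviations, same naming rules.
#' @param io_sd Optional directly estimated IO standard deviation.
#' @return A list with elements `mmd` and `io`, each a list with `mean` and
#'   `sd` (mg/kgBW/d; `sd` is `NA` when no `sds` are supplied).
#' @examples
#' solve_mmd(c(
#'   pto_pp = 2.6, pto_pa = 6.5, egl = 14.5,
#'   ufaap = 0.9, hsnm = 1.5, ol = 0
#' ))
#' @export
solve_mmd <- function(components, constants = model_constants(),
                      sds = NULL, io_sd = NULL) {
  components <- as_loss_components(components, "components")
  r <- constants$io_rate
  s <- sum(components)
  mmd_mean <- s / (1 - r)
  io_mean <- r * mmd_mean

  mmd_sd <- NA_real_
  io_sd_out <- NA_real_
  if (!is.null(sds)) {
    sds <- as_loss_components(sds, "sds")
    io_sd_out <- if (!is.null(io_sd) && !is.na(io_sd)) {
      if (io_sd < 0) stop("io_sd must be non-negative", call. = FALSE)
      io_sd
    } else {
      r * propagate_sd(sds) / (1 - r)
    }
    mmd_sd <- propagate_sd(c(io_sd_out, sds))
  }
  list(
    mmd = list(mean = mmd_mean, sd = mmd_sd),
    io = list(mean = io_mean, sd = io_sd_out)
  )
}

# validate/name a length-6 non-negative component vector
as_loss_components <- function(x, what) {
  nm <- loss_component_names()
  if (!is.numeric(x) || length(x) != 6L) {
    stop(what, " must be a numeric vector of the 6 non-IO loss components",
      call. = FALSE
    )
  }
  if (is.null(names(x))) {
    names(x) <- nm
  } else {
    miss <- setdiff(nm, names(x))
    if (length(miss) > 0L) {
      stop(what, " missing component(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    x <- x[nm]
  }
  if (any(!is.finite(x))) stop(what, " must be finite", call. = FALSE)
  if (any(x < 0)) stop(what, " must be non-negative", call. = FALSE)
  x
}

#' Root-sum-of-squares propagation of standard deviations
#'
#' The standard deviation of a sum of independently estimated loss terms is
#' taken as the square root of the sum of squared term SDs.
#'
#' @param sds Numeric vector of non-negative standard deviations.
#' @return A single non-negative number.
#' @examples
#' propagate_sd(c(3, 4)) # 5
#' @export
propagate_sd <- function(sds) {
  if (!is.numeric(sds) || length(sds) == 0L) {
    stop("sds must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("sds must be finite and non-negative", call. = FALSE)
  }
  sqrt(sum(sds^2))
}

#' Solve the factorial model for every amino acid in a component table
#'
#' Applies [solve_mmd()] to each of the 16 amino acid categories of a loss
#' component table (see [load_pack()] for the schema), then aggregates to
#' total IAA, total DAA and total protein with [aggregate_mmd()].
#'
#' The total-protein row of the source tables treats the hair/skin/nail and
#' miscellaneous component at its aggregate value (5 mg N/kgBW/d converted to
#' protein, 31.25 mg/kgBW/d) rather than as the sum of per-amino-acid HSNM
#' values; both variants are computed and the alternative is reported in the
#' `protein_alt` element together with the difference.
#'
#' @param losses Data frame with columns `aa`, `class`, `<comp>_mean` and
#'   `<comp>_sd` for the six non-IO components, and optionally
#'   `io_sd_override`.
#' @param constants A [model_constants()] object.
#' @param hsnm_total Aggregate HSNM nitrogen (mg N/kgBW/d) used for the
#'   alternative total-protein value; default 5.
#' @return An object of class `mmd_fit`: a list with `per_aa` (data frame of
#'   per-amino-acid components, IO and MMD with SDs), `totals` (total IAA /
#'   DAA / protein), `protein_alt`, and `constants`.
#' @examples
#' pack <- load_pack()
#' fit <- solve_mmd_table(pack$components, pack$constants)
#' fit$totals
#' @export
solve_mmd_table <- function(losses, constants = model_constants(),
                            hsnm_total = 5) {
  losses <- validate_loss_table(losses)
  nm <- loss_component_names()
  per <- losses[, c("aa", "class")]
  for (cn in nm) {
    per[[paste0(cn, "_mean")]] <- losses[[paste0(cn, "_mean")]]
    per[[paste0(cn, "_sd")]] <- losses[[paste0(cn, "_sd")]]
  }
  n <- nrow(per)
  per$io_mean <- per$io_sd <- per$mmd_mean <- per$mmd_sd <- NA_real_
  for (i in seq_len(n)) {
    means <- unlist(per[i, paste0(nm, "_mean")])
    names(means) <- nm
    sds <- unlist(per[i, paste0(nm, "_sd")])
    names(sds) <- nm
    ov <- if ("io_sd_override" %in% names(losses)) {
      losses$io_sd_override[i]
    } else {
      NA_real_
    }
    sol <- solve_mmd(means, constants, sds = sds, io_sd = ov)
    per$mmd_mean[i] <- sol$mmd$mean
    per$mmd_sd[i] <- sol$mmd$sd
    per$io_mean[i] <- sol$io$mean
    per$io_sd[i] <- sol$io$sd
  }
  totals <- aggregate_mmd(per)

  # alternative total-protein value with HSNM at its aggregate nitrogen total
  nonio_tot <- sum(vapply(
    setdiff(nm, "hsnm"),
    function(cn) sum(per[[paste0(cn, "_mean")]]), numeric(1)
  ))
  alt_mmd <- (nonio_tot + constants$n_to_protein * hsnm_total) /
    (1 - constants$io_rate)
  protein_alt <- list(
    mmd_mean = alt_mmd,
    io_mean = constants$io_rate * alt_mmd,
    difference = alt_mmd - totals$mean[totals$group == "total_protein"]
  )

  structure(
    list(
      per_aa = per, totals = totals, protein_alt = protein_alt,
      constants = constants
    ),
    class = "mmd_fit"
  )
}

#' Aggregate per-amino-acid demands to class and protein totals
#'
#' @param per_aa Data frame with columns `aa`, `class`, `mmd_mean` and
#'   (optionally) `mmd_sd` covering all 16 categories.
#' @return Data frame with rows `total_iaa`, `total_daa`, `total_protein`
#'   and columns `group`, `mean`, `sd` (root-sum-of-squares of member SDs).
#' @export
aggregate_mmd <- function(per_aa) {
  if (!all(c("aa", "class", "mmd_mean") %in% names(per_aa))) {
    stop("per_aa must have columns aa, class, mmd_mean", call. = FALSE)
  }
  missing <- setdiff(aa_keys()$aa, per_aa$aa)
  if (length(missing) > 0L) {
    stop("per_aa missing amino acid(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  sds <- if ("mmd_sd" %in% names(per_aa)) per_aa$mmd_sd else rep(NA_real_, nrow(per_aa))
  agg <- function(keep) {
    m <- sum(per_aa$mmd_mean[keep])
    s <- if (all(is.finite(sds[keep]))) propagate_sd(sds[keep]) else NA_real_
    c(mean = m, sd = s)
  }
  iaa <- agg(per_aa$class == "IAA")
  daa <- agg(per_aa$class == "DAA")
  data.frame(
    group = c("total_iaa", "total_daa", "total_protein"),
    mean = c(iaa["mean"], daa["mean"], iaa["mean"] + daa["mean"]),
    sd = c(
      iaa["sd"], daa["sd"],
      if (is.finite(iaa["sd"]) && is.finite(daa["sd"])) {
        propagate_sd(c(iaa["sd"], daa["sd"]))
      } else {
        NA_real_
      }
    ),
    row.names = NULL
  )
}

#' Proportional contribution of each loss source to the demand
#'
#' Expresses each of the seven loss sources (IO, PTO_PP, PTO_PA, EGL, UFAAP,
#' HSNM, OL) as a fraction of the amino acid's MMD, plus the combined total
#' oxidative losses (TOL = IO + PTO_PP + PTO_PA). The seven individual shares
#' sum to 1 by the fixed-point identity.
#'
#' @param fit An `mmd_fit` from [solve_mmd_table()].
#' @param aa Optional character vector restricting the amino acids reported.
#' @return Long data frame with columns `aa`, `source`, `share`. `source`
#'   runs over the seven losses and the derived `tol` row.
#' @export
source_proportions <- function(fit, aa = NULL) {
  stopifnot(inherits(fit, "mmd_fit"))
  per <- fit$per_aa
  if (!is.null(aa)) per <- per[per$aa %in% aa, , drop = FALSE]
  if (any(per$mmd_mean <= 0)) {
    stop("proportions undefined: zero MMD for ",
      paste(per$aa[per$mmd_mean <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  src <- c("io", loss_component_names())
  out <- do.call(rbind, lapply(seq_len(nrow(per)), function(i) {
    vals <- c(
      per$io_mean[i],
      unlist(per[i, paste0(loss_component_names(), "_mean")])
    )
    shares <- vals / per$mmd_mean[i]
    data.frame(
      aa = per$aa[i],
      source = c(src, "tol"),
      share = c(shares, sum(shares[1:3])),
      row.names = NULL
    )
  }))
  out
}

#' Indispensable amino acid share of the total protein demand
#'
#' @param totals Either an `mmd_fit` or its `totals` data frame.
#' @return Percentage (0--100) of total protein demand accounted for by the
#'   indispensable amino acids.
#' @examples
#' # FAO/WHO requirement values give roughly 28%
#' iaa_share(data.frame(
#'   group = c("total_iaa", "total_daa", "total_protein"),
#'   mean = c(184, 476, 660)
#' ))
#' @export
iaa_share <- function(totals) {
  if (inherits(totals, "mmd_fit")) totals <- totals$totals
  prot <- totals$mean[totals$group == "total_protein"]
  iaa <- totals$mean[totals$group == "total_iaa"]
  if (length(prot) != 1L || length(iaa) != 1L) {
    stop("totals must contain total_iaa and total_protein rows", call. = FALSE)
  }
  if (prot <= 0) stop("total protein demand must be positive", call. = FALSE)
  100 * iaa / prot
}

#' @export
print.mmd_fit <- function(x, ...) {
  cat("Factorial minimum metabolic demand fit\n")
  cat(sprintf(
    "  amino acids: %d (%d IAA, %d DAA)\n", nrow(x$per_aa),
    sum(x$per_aa$class == "IAA"), sum(x$per_aa$class == "DAA")
  ))
  t <- x$totals
  for (i in seq_len(nrow(t))) {
    cat(sprintf(
      "  %-14s %7.1f (%s) mg/kgBW/d\n", t$group[i], t$mean[i],
      ifelse(is.na(t$sd[i]), "NA", sprintf("%.1f", t$sd[i]))
    ))
  }
  cat(sprintf(
    "  total protein with aggregate HSNM: %.1f (diff %+.2f)\n",
    x$protein_alt$mmd_mean, x$protein_alt$difference
  ))
  invisible(x)
}
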