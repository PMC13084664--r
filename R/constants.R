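#' Model constants of the factorial demand model
#'
#' Bundles the scalar constants of the model. Defaults describe the healthy
#' young adult male reference subject:
#'
#' * `io_rate` -- fraction of each absorbed dietary amino acid lost to
#'   inevitable (constitutive first-pass) oxidation; default 0.29. The
#'   factorial equation is solved with denominator `1 - io_rate`, so the rate
#'   must lie strictly below 1.
#' * `pto_pa_fraction`, `pto_pp_fraction` -- fractions of postabsorptive and
#'   postprandial protein breakdown lost to turnover-associated oxidation
#'   (0.11 and 0.024). These are carried for reference: the packaged parameter
#'   tables supply the turnover-oxidation *values* per amino acid directly,
#'   not breakdown rates.
#' * `n_to_protein` -- nitrogen-to-protein conversion factor (6.25).
#' * `body_weight` -- reference body weight in kg (75), used to convert per-day
#'   excretions to per-kg values.
#' * `creatinine_excretion` -- urinary creatinine excretion in mmol/kgBW/d
#'   (0.2), used to convert creatinine-normalised excretion records.
#'
#' @param io_rate Inevitable-oxidation fraction in (0, 1).
#' @param pto_pa_fraction,pto_pp_fraction Turnover-oxidation fractions.
#' @param n_to_protein Nitrogen-to-protein factor.
#' @param body_weight Reference body weight, kg.
#' @param creatinine_excretion Creatinine excretion, mmol/kgBW/d.
#' @return An object of class `model_constants` (a named list).
#' @examples
#' model_constants()
#' @export
model_constants <- function(io_rate = 0.29,
                            pto_pa_fraction = 0.11,
                            pto_pp_fraction = 0.024,
                            n_to_protein = 6.25,
                            body_weight = 75,
                            creatinine_excretion = 0.2) {
  stopifnot(
    is.numeric(io_rate), length(io_rate) == 1L, is.finite(io_rate),
    is.numeric(n_to_protein), n_to_protein > 0,
    is.numeric(body_weight), body_weight > 0,
    is.numeric(creatinine_excretion), creatinine_excretion >= 0
  )
  if (io_rate >= 1) {
    stop("infeasible model: io_rate must be < 1 (denominator 1 - io_rate)",
      call. = FALSE
    )
  }
  if (io_rate <= 0) {
    stop("io_rate must be positive", call. = FALSE)
  }
  structure(
    list(
      io_rate = io_rate,
      pto_pa_fraction = pto_pa_fraction,
      pto_pp_fraction = pto_pp_fraction,
      n_to_protein = n_to_protein,
      body_weight = body_weight,
      creatinine_excretion = creatinine_excretion
    ),
    class = "model_constants"
  )
}

#' Read model constants from a YAML or JSON file
#'
#' Any field absent from the file keeps its default. Unknown fields are an
#' error, so typos in a configuration file do not pass silently.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `model_constants` object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("no such constants file: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(model_constants))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown constants field(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(model_constants, vals)
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Factorial model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}
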