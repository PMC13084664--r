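#' Load a parameter pack
#'
#' A parameter pack is a directory of small CSV/YAML files holding every
#' input of the factorial model. The packaged default (under
#' `system.file("extdata", package = "aademand")`) transcribes the source
#' study's parameter tables for the 75-kg young adult male. Files:
#'
#' * `loss_components.csv` -- per-amino-acid non-IO obligatory losses:
#'   columns `aa`, `class`, `<comp>_mean`/`<comp>_sd` for `pto_pp`, `pto_pa`,
#'   `egl`, `ufaap`, `hsnm`, `ol`, plus `io_sd_override` (directly estimated
#'   IO SDs; `NA` to fall back to scaled root-sum-of-squares) and
#'   `printed_mmd` (the source table's MMD column, kept for regression
#'   checks only -- never used in computation).
#' * `constants.yaml` -- overrides for [model_constants()].
#' * `requirements.csv` -- demand/requirement comparison values per IAA and
#'   for total protein: columns `aa`, `mmd_demand`, `fao_requirement`
#'   (mg/kgBW/d, integer as published) and `body_protein` (mg/g).
#' * `protein_totals.csv` -- the published total-protein component row
#'   (`component`, `mean`, `sd`), a transcription used for regression checks.
#' * `reference_ratios.csv` -- digestible reference ratios per protein
#'   source and scoring pattern: `source`, `pattern` (`MMD`/`FAO`), `aa`,
#'   `ratio`.
#' * `body_composition.csv`, `dermal_composition_synthetic.csv`,
#'   `urinary_records_synthetic.csv`, `metabolite_records_synthetic.csv` --
#'   inputs for the loss-derivation operations ([derive_hsnm()],
#'   [derive_ufaap()], [assemble_ol()]). Files suffixed `_synthetic` are
#'   back-derived stand-ins for unpublished appendix datasets, constructed so
#'   the derivation operations reproduce the published loss columns.
#'
#' @param path Directory containing the pack files; default is the packaged
#'   pack.
#' @return An object of class `aa_pack`: a list with elements `components`,
#'   `constants`, `requirements`, `protein_totals`, `reference_ratios`,
#'   `body_composition`, `dermal_composition`, `urinary_records`,
#'   `metabolite_records`.
#' @examples
#' pack <- load_pack()
#' head(pack$components)
#' @export
load_pack <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "aademand")
  }
  if (file.exists(path) && !dir.exists(path)) {
    stop("schema error: pack path must be a directory of pack files, got a file: ",
      path,
      call. = FALSE
    )
  }
  if (!dir.exists(path)) stop("no such pack directory: ", path, call. = FALSE)

  read_pack_csv <- function(file, required) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      stop("schema error: pack file missing: ", file, call. = FALSE)
    }
    df <- tryCatch(
      utils::read.csv(fp, stringsAsFactors = FALSE, comment.char = "#"),
      error = function(e) {
        stop("parse error in ", file, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    if (nrow(df) == 0L) {
      stop("schema error: ", file, " is empty", call. = FALSE)
    }
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L) {
      stop("schema error: ", file, " missing column(s): ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    df
  }

  comp_cols <- c(
    "aa", "class",
    paste0(rep(loss_component_names(), each = 2), c("_mean", "_sd")),
    "io_sd_override"
  )
  components <- validate_loss_table(
    read_pack_csv("loss_components.csv", comp_cols)
  )

  constants_path <- file.path(path, "constants.yaml")
  constants <- if (file.exists(constants_path)) {
    read_constants(constants_path)
  } else {
    model_constants()
  }

  requirements <- read_pack_csv(
    "requirements.csv",
    c("aa", "mmd_demand", "fao_requirement", "body_protein")
  )
  protein_totals <- read_pack_csv("protein_totals.csv", c("component", "mean", "sd"))
  reference_ratios <- read_pack_csv(
    "reference_ratios.csv", c("source", "pattern", "aa", "ratio")
  )
  body_composition <- read_pack_csv("body_composition.csv", c("aa", "mg_per_g"))
  dermal_composition <- read_pack_csv(
    "dermal_composition_synthetic.csv", c("aa", "mg_per_g")
  )
  urinary_records <- read_pack_csv(
    "urinary_records_synthetic.csv",
    c("study", "aa", "unit", "mean", "sd", "n_subjects", "body_weight")
  )
  metabolite_records <- read_pack_csv(
    "metabolite_records_synthetic.csv",
    c(
      "metabolite", "parent_aa", "excretion", "excretion_sd", "unit",
      "stoichiometry"
    )
  )

  structure(
    list(
      components = components,
      constants = constants,
      requirements = requirements,
      protein_totals = protein_totals,
      reference_ratios = reference_ratios,
      body_composition = body_composition,
      dermal_composition = dermal_composition,
      urinary_records = urinary_records,
      metabolite_records = metabolite_records
    ),
    class = "aa_pack"
  )
}

#' Validate a loss component table
#'
#' Checks the schema of a per-amino-acid component table: all 16 categories
#' present exactly once, classes consistent with [aa_keys()], all component
#' cells numeric, finite and non-negative.
#'
#' @param losses Data frame to validate.
#' @return The table, rows ordered as [aa_keys()].
#' @export
validate_loss_table <- function(losses) {
  if (!is.data.frame(losses)) {
    stop("loss table must be a data frame", call. = FALSE)
  }
  need <- c(
    "aa", "class",
    paste0(rep(loss_component_names(), each = 2), c("_mean", "_sd"))
  )
  miss <- setdiff(need, names(losses))
  if (length(miss) > 0L) {
    stop("loss table missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  keys <- aa_keys()
  missing_aa <- setdiff(keys$aa, losses$aa)
  if (length(missing_aa) > 0L) {
    stop("loss table missing amino acid(s): ",
      paste(missing_aa, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(losses$aa)) {
    stop("loss table has duplicated amino acid rows", call. = FALSE)
  }
  losses <- losses[match(keys$aa, losses$aa), , drop = FALSE]
  if (!identical(losses$class, keys$class)) {
    stop("loss table class column inconsistent with amino acid categories",
      call. = FALSE
    )
  }
  num_cols <- setdiff(need, c("aa", "class"))
  for (cn in num_cols) {
    v <- losses[[cn]]
    if (!is.numeric(v)) {
      bad <- which(!grepl("^\\s*[-0-9.eE+]*\\s*$", as.character(v)))[1]
      stop("parse error: non-numeric cell in column ", cn, ", row ",
        ifelse(is.na(bad), 1L, bad),
        call. = FALSE
      )
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("loss table column ", cn, " must be finite and non-negative",
        call. = FALSE
      )
    }
  }
  rownames(losses) <- NULL
  losses
}

#' Write a parameter pack back to disk
#'
#' Inverse of [load_pack()]; numeric columns round-trip losslessly at 15
#' significant digits.
#'
#' @param pack An `aa_pack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pack <- function(pack, dir) {
  stopifnot(inherits(pack, "aa_pack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  wr(pack$components, "loss_components.csv")
  yaml::write_yaml(
    unclass(pack$constants), file.path(dir, "constants.yaml"),
    precision = 15L
  )
  wr(pack$requirements, "requirements.csv")
  wr(pack$protein_totals, "protein_totals.csv")
  wr(pack$reference_ratios, "reference_ratios.csv")
  wr(pack$body_composition, "body_composition.csv")
  wr(pack$dermal_composition, "dermal_composition_synthetic.csv")
  wr(pack$urinary_records, "urinary_records_synthetic.csv")
  wr(pack$metabolite_records, "metabolite_records_synthetic.csv")
  invisible(dir)
}

#' @export
print.aa_pack <- function(x, ...) {
  cat("Factorial model parameter pack\n")
  cat(sprintf("  component rows: %d amino acids\n", nrow(x$components)))
  cat(sprintf(
    "  protein sources: %s\n",
    paste(unique(x$reference_ratios$source), collapse = ", ")
  ))
  invisible(x)
}
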