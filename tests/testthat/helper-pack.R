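# cache the packaged pack and its solved fit across test files
.cache <- new.env(parent = emptyenv())

default_pack <- function() {
  if (is.null(.cache$pack)) .cache$pack <- load_pack()
  .cache$pack
}

default_fit <- function() {
  if (is.null(.cache$fit)) {
    p <- default_pack()
    .cache$fit <- solve_mmd_table(p$components, p$constants)
  }
  .cache$fit
}

# a minimal all-zero loss table (degenerate input)
zero_loss_table <- function() {
  keys <- aa_keys()
  df <- data.frame(aa = keys$aa, class = keys$class)
  for (cn in c("pto_pp", "pto_pa", "egl", "ufaap", "hsnm", "ol")) {
    df[[paste0(cn, "_mean")]] <- 0
    df[[paste0(cn, "_sd")]] <- 0
  }
  df$io_sd_override <- NA_real_
  df
}

# named per-AA vector of a component column from the pack
pack_column <- function(col) {
  p <- default_pack()$components
  stats::setNames(p[[col]], p$aa)
}
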