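# Species presets: structured-text (YAML) parameter files shipped with the
# package, each value tagged with its provenance ("lineage" = inherited from
# the antecedent sleep-switch/pacemaker model family, "fitted" = constrained
# here against the behavioral targets described in the vignette,
# "convention" = definitional choice).

.preset_names <- c("human_nominal", "rodent_generic", "degu",
                   "squirrel_monkey", "primate_generic")

#' Load a species parameter preset
#'
#' Reads one of the shipped structured-text presets and returns a validated
#' parameter set plus per-parameter provenance notes.
#'
#' @param name one of `"human_nominal"`, `"rodent_generic"`, `"degu"`,
#'   `"squirrel_monkey"`, `"primate_generic"`.
#' @return object of class `species_preset`: list with `name`, `params`
#'   (a `model_params`), `provenance` (named character), `description`.
#' @examples
#' load_preset("degu")$params$pacemaker$tau_c_h  # 23.0
#' @export
load_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% .preset_names)) {
    stop("unknown preset: ", paste(name, collapse = ", "),
         "; available: ", paste(.preset_names, collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "nichesim")
  if (!nzchar(path)) stop("preset file missing for ", name, call. = FALSE)
  read_preset(path)
}

#' Read a preset file
#'
#' @param path path to a preset YAML file.
#' @return `species_preset`.
#' @export
read_preset <- function(path) {
  y <- yaml::read_yaml(path)
  for (fld in c("name", "params")) {
    if (is.null(y[[fld]])) stop("preset missing field: ", fld, call. = FALSE)
  }
  pars <- y$params
  p <- model_params(
    switch_ = pars$switch_,
    homeostat = pars$homeostat,
    pacemaker = pars$pacemaker,
    photic = pars$photic,
    relay = pars$relay,
    wake_threshold = if (is.null(pars$wake_threshold)) 1 else
      pars$wake_threshold
  )
  # every numeric field must be spelled out in the file (no silent defaults)
  for (blk in c("switch_", "homeostat", "pacemaker", "photic", "relay")) {
    missing <- setdiff(names(p[[blk]]), names(pars[[blk]]))
    if (length(missing)) {
      stop("preset ", y$name, " missing ", blk, " fields: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = y$name, params = p,
                 provenance = unlist(y$provenance),
                 description = y$description %||% ""),
            class = "species_preset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a preset file
#'
#' Serializes a `species_preset` back to YAML; `read_preset()` of the result
#' reproduces the preset exactly.
#'
#' @param preset a `species_preset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preset <- function(preset, path) {
  stopifnot(inherits(preset, "species_preset"))
  p <- preset$params
  y <- list(
    name = preset$name,
    description = preset$description,
    params = list(
      switch_ = p$switch_, homeostat = p$homeostat,
      pacemaker = p$pacemaker, photic = p$photic, relay = p$relay,
      wake_threshold = p$wake_threshold
    ),
    provenance = as.list(preset$provenance)
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @export
print.species_preset <- function(x, ...) {
  cat(sprintf("<species_preset> %s\n", x$name))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  print(x$params)
  invisible(x)
}
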