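ALIAS_MAP <- c(effectAntiMet = "alpha", effectProMet = "beta",
               conversionThreshold = "theta", effectPerTumorCell = "kappa",
               switchSensitivity = "switch_sensitivity",
               divisionSensitivity = "division_sensitivity")

#' Load a simulation configuration from a YAML file
#'
#' Reads a structured plain-text (YAML) configuration, resolves defaults for
#' any omitted field, and validates everything through [sim_config()]. A
#' minimal file containing only `seed: 1` yields the full default
#' configuration. Inside the `interaction` block the canonical field names
#' may be replaced by their tabulated aliases (`effectAntiMet`,
#' `effectProMet`, `conversionThreshold`, `effectPerTumorCell`,
#' `switchSensitivity`, `divisionSensitivity`). Unknown keys and
#' out-of-range values are rejected with errors naming the field.
#'
#' @param path Path to the YAML file.
#' @return A validated [sim_config()] object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_keys <- c("rows", "cols", "n_steps", "density", "pattern",
                "switching_enabled", "interaction", "chemo", "seed")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  inter <- raw$interaction
  if (!is.null(inter)) {
    names(inter) <- ifelse(names(inter) %in% names(ALIAS_MAP),
                           ALIAS_MAP[names(inter)], names(inter))
    allowed <- names(formals(interaction_params))
    unknown <- setdiff(names(inter), allowed)
    if (length(unknown))
      stop(sprintf("unknown interaction key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    inter <- do.call(interaction_params, inter)
  } else inter <- interaction_params()
  ch <- raw$chemo
  if (!is.null(ch)) {
    allowed <- names(formals(chemo_params))
    unknown <- setdiff(names(ch), allowed)
    if (length(unknown))
      stop(sprintf("unknown chemo key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    ch <- do.call(chemo_params, ch)
  }
  args <- raw[setdiff(intersect(names(raw), top_keys),
                      c("interaction", "chemo"))]
  args$interaction <- inter
  args$chemo <- ch
  do.call(sim_config, args)
}

#' Save a simulation configuration to YAML
#'
#' Writes the configuration with canonical field names;
#' `load_config(save_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config A [sim_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$interaction <- unclass(x$interaction)
  x$interaction$i_max <- NULL # derived
  if (!is.null(x$chemo)) x$chemo <- unclass(x$chemo) else x$chemo <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a grid snapshot as plain text
#'
#' State grids are written as an integer matrix (codes 0=EMPTY, 1=TUMOR,
#' 2=ASTRO_ANTI, 3=ASTRO_PRO, 4=NEUTRAL), one row per line, space-separated;
#' drug grids as full-precision reals in the same layout. Round trips are
#' bit-exact.
#'
#' @param x An `astro_world`, or a matrix.
#' @param path Output path.
#' @param what For a world: `"states"` (default) or `"drug"`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(x, path, what = c("states", "drug")) {
  what <- match.arg(what)
  m <- if (inherits(x, "astro_world")) x[[what]] else x
  lines <- if (is.integer(m) || all(m == round(m))) {
    apply(m, 1, paste, collapse = " ")
  } else {
    apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a grid snapshot
#'
#' @param path Path to a snapshot written by [write_snapshot()].
#' @param what `"states"` validates integer codes 0--4 and returns an
#'   integer matrix; `"drug"` returns a numeric matrix.
#' @return A matrix; malformed lines raise an error with the line number.
#' @export
read_snapshot <- function(path, what = c("states", "drug")) {
  what <- match.arg(what)
  lines <- readLines(path)
  if (!length(lines)) stop("empty snapshot file", call. = FALSE)
  parsed <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (any(is.na(v)))
      stop(sprintf("snapshot parse error at line %d", i), call. = FALSE)
    v
  })
  ncols <- lengths(parsed)
  if (length(unique(ncols)) != 1)
    stop(sprintf("snapshot parse error at line %d: ragged row",
                 which(ncols != ncols[1])[1]), call. = FALSE)
  m <- do.call(rbind, parsed)
  if (what == "states") {
    bad <- which(!(m %in% 0:4))
    if (length(bad))
      stop(sprintf("invalid state code at line %d",
                   ((bad[1] - 1) %% nrow(m)) + 1), call. = FALSE)
    storage.mode(m) <- "integer"
  }
  m
}

#' Build a run manifest
#'
#' Provenance record for a set of replicate runs: a hash of the canonical
#' configuration, the base seed, the derived per-replicate seeds, package
#' version, output paths and a timestamp. Every emitted table row is
#' traceable to `(config_hash, seed)`, and re-running a manifest reproduces
#' the outputs.
#'
#' @param config A [sim_config()] object.
#' @param base_seed Base seed of the run set.
#' @param n_replicates Number of replicates.
#' @param outputs Character vector of output file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, base_seed = config$seed, n_replicates = 1L,
                         outputs = character(0)) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       base_seed = as.integer(base_seed),
       replicate_seeds = replicate_seed(base_seed, seq_len(n_replicates)),
       version = as.character(utils::packageVersion("astroabm")),
       outputs = outputs,
       timestamp = format(Sys.time(), tz = "UTC")) -> m
  class(m) <- "run_manifest"
  m
}

#' Write a run manifest to YAML
#'
#' @param manifest A [run_manifest()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
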