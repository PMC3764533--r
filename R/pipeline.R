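## End-to-end orchestration: alignment -> column profile -> LVR delimitation
## -> length table -> synapomorphy scan, with a reproducible manifest.

#' Pipeline configuration
#'
#' All stage parameters default to the package-wide defaults; every field
#' can be overridden. Configurations can also be read from a single YAML
#' file with the same keys.
#'
#' @param msa_path Path to the input alignment.
#' @param msa_format `"fasta"` or `"stockholm"`.
#' @param clade_path Path to a clade map (Newick or rank table CSV).
#' @param clade_unions Character vector of `"X+Y"` compound-clade
#'   declarations.
#' @param out_dir Output directory.
#' @param gap_threshold,min_conserved_block,min_lvr_cols,label_scheme
#'   Delimitation parameters (see [delimit_lvrs()]).
#' @param min_share,outside_max_freq Scan parameters (see
#'   [flag_synapomorphies()]).
#' @param model_path Optional helix-table CSV to score against the
#'   alignment.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed is forwarded to any downstream randomized
#'   consumers).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(msa_path, clade_path, out_dir,
                            msa_format = c("fasta", "stockholm"),
                            clade_unions = character(0),
                            gap_threshold = 0.2,
                            min_conserved_block = 5L,
                            min_lvr_cols = 2L,
                            label_scheme = "alpha",
                            min_share = 0.9,
                            outside_max_freq = 0.5,
                            model_path = NULL,
                            seed = 1L) {
  structure(
    list(
      msa_path = msa_path, msa_format = match.arg(msa_format),
      clade_path = clade_path, clade_unions = clade_unions,
      out_dir = out_dir,
      gap_threshold = gap_threshold,
      min_conserved_block = as.integer(min_conserved_block),
      min_lvr_cols = as.integer(min_lvr_cols),
      label_scheme = label_scheme,
      min_share = min_share, outside_max_freq = outside_max_freq,
      model_path = model_path,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full LVR pipeline
#'
#' Reads the alignment and clade map, delimits LVRs, measures per-sequence
#' region lengths, scans the named clades for candidate synapomorphies, and
#' writes every artifact plus a manifest recording parameters, seed and
#' input/output checksums. Reruns with the same config are byte-identical.
#' Clade members missing from the alignment are dropped with a warning and
#' listed in the manifest.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list with `region_map`, `profile`, `lengths`,
#'   `candidates`, `report`, optional `model_score`, and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  aln <- tryCatch(
    read_msa(config$msa_path, config$msa_format),
    error = function(e) {
      stop("[read_msa] ", conditionMessage(e), call. = FALSE)
    }
  )
  clades <- tryCatch(
    read_clade_map(config$clade_path, unions = config$clade_unions),
    error = function(e) {
      stop("[read_clade_map] ", conditionMessage(e), call. = FALSE)
    }
  )
  # drop clade members with no sequence in the alignment
  excluded <- setdiff(clades$terminals, aln$ids)
  if (length(excluded) > 0L) {
    warning(
      "clade map terminal(s) missing from alignment, excluded: ",
      paste(excluded, collapse = ", "),
      call. = FALSE
    )
    kept <- lapply(clades$clades, intersect, y = aln$ids)
    kept <- kept[vapply(kept, length, 0L) > 0L]
    clades <- clade_map(intersect(clades$terminals, aln$ids), kept)
  }
  profile <- column_profile(aln, gap_threshold = config$gap_threshold)
  map <- delimit_lvrs(
    profile,
    min_conserved_block = config$min_conserved_block,
    min_lvr_cols = config$min_lvr_cols,
    label_scheme = config$label_scheme
  )
  lengths <- lvr_lengths(aln, map)
  candidates <- flag_synapomorphies(
    lengths, clades,
    min_share = config$min_share,
    outside_max_freq = config$outside_max_freq
  )
  report <- report_table(candidates, "text")
  score <- NULL
  if (!is.null(config$model_path)) {
    model <- read_model_csv(config$model_path, n_cols = aln$n_cols)
    score <- model_score(model, aln)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    region_map = file.path(config$out_dir, "regions.csv"),
    lengths = file.path(config$out_dir, "lengths.csv"),
    candidates = file.path(config$out_dir, "candidates.csv"),
    report = file.path(config$out_dir, "report.txt"),
    manifest = file.path(config$out_dir, "manifest.yaml")
  )
  write_region_map(map, paths[["region_map"]])
  utils::write.csv(
    as.data.frame(lengths), paths[["lengths"]],
    row.names = FALSE, quote = FALSE
  )
  writeLines(report_table(candidates, "csv"), paths[["candidates"]])
  writeLines(report, paths[["report"]])
  manifest <- list(
    parameters = list(
      msa_format = config$msa_format,
      gap_threshold = config$gap_threshold,
      min_conserved_block = config$min_conserved_block,
      min_lvr_cols = config$min_lvr_cols,
      label_scheme = config$label_scheme,
      min_share = config$min_share,
      outside_max_freq = config$outside_max_freq,
      seed = config$seed
    ),
    inputs = as.list(unclass(tools::md5sum(
      c(config$msa_path, config$clade_path)
    ))),
    excluded_terminals = as.list(excluded),
    outputs = as.list(unclass(tools::md5sum(unname(
      paths[setdiff(names(paths), "manifest")]
    ))))
  )
  if (!is.null(score)) {
    manifest$model_score <- list(
      total = score$total, min_per_row = score$min_per_row,
      n_helices = score$n_helices
    )
  }
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(list(
    region_map = map, profile = profile, lengths = lengths,
    candidates = candidates, report = report, model_score = score,
    paths = paths
  ))
}
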