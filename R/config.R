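#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline in one flat list. Defaults
#' are the study-standard analysis settings: a 0.001% clonotype frequency cutoff, a
#' 20-fold threshold for merging 1-bp neighbours, a 5-nt minimum D-segment
#' match, 0.8 matrix-similarity thresholds, +/-7 nt heptamer windows, a 4-nt
#' minimum RUNX1-heptamer overlap, 12+/-1 and 23+/-1 bp RSS spacer classes,
#' partial-heptamer spacer classes {12} and 19-25 bp, and 60-bp deletion-end
#' inner spans.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `vdj_config`.
#' @export
#' @examples
#' cfg <- vdj_config(clonotype_frequency_cutoff = 0)
#' cfg$merge_fold_threshold
vdj_config <- function(...) {
  cfg <- list(
    clonotype_frequency_cutoff = 1e-5,
    merge_fold_threshold = 20,
    min_d_match = 5L,
    similarity_threshold_runx1 = 0.8,
    similarity_threshold_heptamer = 0.8,
    similarity_threshold_nonamer = 0.8,
    window_flank = 7L,
    min_runx1_heptamer_overlap = 4L,
    spacer_classes = list(c(11L, 13L), c(22L, 24L)),
    partial_spacer_classes = list(c(12L, 12L), c(19L, 25L)),
    region_inner_span = 60L,
    join_min_overlap = 10L,
    join_max_mismatch_frac = 0.25,
    assign_min_ident = 0.9,
    assign_min_len = 15L,
    cutoff_before_merge = FALSE,
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @rdname vdj_config
#' @param path Path to a flat YAML file whose keys mirror the config fields.
#' @export
read_vdj_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  # command-style overrides in `...` beat file values
  do.call(vdj_config, utils::modifyList(vals, list(...)))
}

validate_config <- function(cfg) {
  fracs <- c(
    "similarity_threshold_runx1", "similarity_threshold_heptamer",
    "similarity_threshold_nonamer", "join_max_mismatch_frac", "assign_min_ident"
  )
  for (f in fracs) {
    if (!(cfg[[f]] > 0 && cfg[[f]] <= 1)) abort(sprintf("%s must be in (0, 1]", f))
  }
  if (cfg$clonotype_frequency_cutoff < 0 || cfg$clonotype_frequency_cutoff > 1) {
    abort("clonotype_frequency_cutoff must be in [0, 1]")
  }
  lens <- c(
    "min_d_match", "window_flank", "min_runx1_heptamer_overlap",
    "region_inner_span", "join_min_overlap", "assign_min_len"
  )
  for (f in lens) {
    if (!(cfg[[f]] >= 1)) abort(sprintf("%s must be a positive integer", f))
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$merge_fold_threshold <= 0) abort("merge_fold_threshold must be positive")
  structure(cfg, class = c("vdj_config", "list"))
}
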