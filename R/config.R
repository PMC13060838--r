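#' Pipeline configuration defaults
#'
#' All tunable thresholds of the pipeline with their defaults: FDR 0.1 for
#' both screens, a 1.5 kb proximal window around the TSS, no LFC gate at
#' link calling, a 1 Mb hard distance cut for high-confidence enhancers, and
#' the cascade gates (adjusted p < 0.1 with an |log2FC| threshold offered at
#' the two presets 0.2 and 0.1).
#'
#' @return nested named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    synth = list(
      annotation_params = list(),
      regulatory_params = list(),
      cre_screen = list(n_cells = 12000L, grna_per_target = 8L,
                        n_control_promoters = 5L),
      promoter_screen = list(n_cells = 8000L, grna_per_target = 3L,
                             n_target_genes = 40L, propagate_trans = TRUE)
    ),
    qc = list(min_umi = 100, min_genes = 10, min_cells_per_grna = 10,
              normalization_scale = 1e4),
    de = list(fdr = 0.1, shrink_weight = 0.75, min_cells_per_group = 10,
              n_variable_genes = 300L),
    links = list(proximal_window = 1500, fdr = 0.1, min_abs_lfc = 0),
    prioritize = list(max_distance = 1e6, apply_max_distance = TRUE),
    enrichment = list(min_targets = 50L, min_degs = 5L, deg_adj_p = 0.1,
                      deg_min_abs_lfc = 0.5),
    cascade = list(adj_p_max = 0.1, min_abs_lfc = 0.2, top_k = Inf,
                   min_shared = 5L, include_hop2_in_programs = FALSE)
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) stop_config("config section '%s' must be a mapping", path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_config("unknown config key(s)%s: %s (valid: %s)",
                if (nzchar(path)) sprintf(" under '%s'", path) else "",
                paste(unknown, collapse = ", "),
                paste(names(defaults), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !k %in% c("annotation_params", "regulatory_params")) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     if (nzchar(path)) paste0(path, ".", k) else k)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, field) if (!ok) stop_config("invalid value for '%s'", field)
  chk(cfg$links$proximal_window > 0, "links.proximal_window")
  chk(cfg$links$fdr > 0 && cfg$links$fdr < 1, "links.fdr")
  chk(cfg$links$min_abs_lfc >= 0, "links.min_abs_lfc")
  chk(cfg$de$fdr > 0 && cfg$de$fdr < 1, "de.fdr")
  chk(cfg$de$shrink_weight >= 0 && cfg$de$shrink_weight <= 1, "de.shrink_weight")
  chk(cfg$prioritize$max_distance > 0, "prioritize.max_distance")
  chk(cfg$cascade$adj_p_max > 0 && cfg$cascade$adj_p_max <= 1, "cascade.adj_p_max")
  chk(cfg$cascade$min_abs_lfc >= 0, "cascade.min_abs_lfc")
  chk(cfg$qc$min_cells_per_grna >= 1, "qc.min_cells_per_grna")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take documented defaults; unknown keys are rejected with the
#' list of valid keys; out-of-range thresholds raise a configuration error.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return validated nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- .merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}
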