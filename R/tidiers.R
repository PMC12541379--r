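#' Broom-style tidiers for result objects
#'
#' `tidy()` returns the per-item table of a result (hierarchy nodes, branch
#' members, sampled pair distances, query neighbours); `glance()` returns a
#' one-row summary.
#'
#' @param x A result object (`phage_hierarchy`, `phage_branch`,
#'   `threshold_report`, `ami_profile`, `phage_query`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL
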