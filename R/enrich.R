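#' Fisher over-representation analysis of a feature set
#'
#' One-sided Fisher's exact test (equivalently the hypergeometric upper
#' tail) for enrichment of each pathway's members in a selected feature set
#' against an annotated background. No multiple-testing correction is applied
#' to the pass flag (the raw-p convention); a Benjamini-Hochberg column is
#' reported for transparency.
#'
#' @param selected Character vector of selected feature ids (subset of
#'   `background`).
#' @param background Character vector of background feature ids (the
#'   annotated universe).
#' @param pathways Named list mapping pathway id to a character vector of
#'   member feature ids, or a two-column data frame (`feature_id`,
#'   `pathway_id`).
#' @param alpha Strict raw p-value threshold for the pass flag.
#' @return Tibble sorted by p-value with one row per pathway: `pathway_id`,
#'   `hits`, `set_size`, `pathway_size`, `background_size`, `p_value`,
#'   `p_adjust` (BH), `pass`.
#' @examples
#' paths <- list(pw1 = c("a", "b", "c"), pw2 = c("d", "e"))
#' fisher_ora(c("a", "b"), letters[1:10], paths)
#' @export
fisher_ora <- function(selected, background, pathways, alpha = 0.01) {
  selected <- unique(selected)
  background <- unique(background)
  extra <- setdiff(selected, background)
  if (length(extra) > 0) {
    abort(sprintf(
      "Selected features outside the background: %s",
      paste(head(extra, 5), collapse = ", ")
    ))
  }
  if (is.data.frame(pathways)) {
    pathways <- split(pathways[[1]], pathways[[2]])
  }
  stopifnot(length(pathways) > 0, !is.null(names(pathways)))

  n_bg <- length(background)
  n_set <- length(selected)
  rows <- purrr::imap_dfr(pathways, function(members, pid) {
    members <- intersect(unique(members), background)
    hits <- length(intersect(members, selected))
    k_path <- length(members)
    ## upper tail of Hypergeometric(n_bg, k_path, n_set) at >= hits
    p <- phyper(hits - 1, k_path, n_bg - k_path, n_set, lower.tail = FALSE)
    tibble::tibble(
      pathway_id = pid, hits = hits, set_size = n_set,
      pathway_size = k_path, background_size = n_bg, p_value = p
    )
  })
  rows$p_adjust <- p.adjust(rows$p_value, method = "BH")
  rows$pass <- rows$p_value < alpha
  dplyr::arrange(rows, .data$p_value, .data$pathway_id)
}
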