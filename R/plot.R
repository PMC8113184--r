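#' Per-case stacked ACS report
#'
#' One stacked bar per case showing the four ACS components (BM thickening,
#' BM reduplication, endothelial activation, ensheathment); bar heights sum
#' to the case AS score. Cases are laid out in the severity ordering of
#' [orderCases()] (VAS, then AS, then id), annotated above each bar with
#' the VAS score and the finding flags (T = tubuloreticular inclusions
#' present, M = myophagocytosis, N = nuclear inclusions), and faceted by
#' study group.
#'
#' @param cohort a \linkS4class{CapillaryCohort}.
#' @return a ggplot object.
#' @export
plotAcsReport <- function(cohort) {
  ord <- orderCases(cohort)
  acs <- acsScore(cohort)
  flags <- deriveFindingsFlags(cohort)
  long <- do.call(rbind, lapply(.SCORE_CATEGORIES, function(cc)
    data.frame(case_id = acs$case_id, category = cc, acs = acs[[cc]],
               stringsAsFactors = FALSE)))
  long$case_id <- factor(long$case_id, levels = ord$case_id)
  long$category <- factor(long$category, levels = rev(.SCORE_CATEGORIES),
                          labels = rev(c("BM thickening", "BM reduplication",
                                         "endothelial activation",
                                         "ensheathment")))
  long$group_label <- ord$group_label[match(as.character(long$case_id),
                                            ord$case_id)]
  ann <- merge(ord, flags, by = "case_id")
  ann$label <- paste0("VAS ", formatC(ann$vas, format = "fg"),
                      ifelse(ann$tri_present, " T", ""),
                      ifelse(ann$myophagocytosis, " M", ""),
                      ifelse(ann$nuclear_inclusions, " N", ""))
  ann$case_id <- factor(ann$case_id, levels = ord$case_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$case_id, y = .data$acs,
                                     fill = .data$category)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_text(data = ann, inherit.aes = FALSE, size = 2.4,
                       angle = 90, hjust = 0,
                       ggplot2::aes(x = .data$case_id, y = .data$as + 0.1,
                                    label = .data$label)) +
    ggplot2::facet_grid(. ~ group_label, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = NULL, y = "ACS score (stacked; total = AS)") +
    ggplot2::ylim(0, 8.6) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   legend.position = "bottom")
}
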