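#' Sample quantitative maps over labeled ROIs
#'
#' Averages each metric map over every region x hemisphere ROI and returns
#' the long-format sample table the statistics chain consumes; each side is
#' recorded as a separate sample.
#'
#' @param labels integer label volume (codes as in the phantom label table).
#' @param label_table data frame mapping `code` to `region`, `hemisphere`.
#' @param quant optional `quant_maps` ([quantify_volume()]); contributes
#'   `apt_weighted` and `total_cest`.
#' @param tensor optional `tensor_maps` ([fit_tensor()]); contributes `fa`
#'   and `md`.
#' @param subject_id,group,stage metadata attached to every row.
#' @return data frame of class `roi_table` with columns `subject_id`,
#'   `group`, `stage`, `region`, `hemisphere`, `metric`, `value`.
#' @export
extract_roi_table <- function(labels, label_table, quant = NULL, tensor = NULL,
                              subject_id = "S01", group = "control",
                              stage = "control") {
  maps <- list()
  if (!is.null(quant)) {
    stop_if_not(inherits(quant, "quant_maps"), "quant must be quant_maps")
    maps$apt_weighted <- quant$apt_weighted
    maps$total_cest <- quant$total_cest
  }
  if (!is.null(tensor)) {
    stop_if_not(inherits(tensor, "tensor_maps"), "tensor must be tensor_maps")
    maps$fa <- tensor$fa
    maps$md <- tensor$md
  }
  stop_if_not(length(maps) > 0, "provide quant and/or tensor maps")
  rows <- list()
  for (i in seq_len(nrow(label_table))) {
    vox <- which(labels == label_table$code[i])
    for (m in names(maps)) {
      vals <- maps[[m]][vox]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, group = group, stage = stage,
        region = label_table$region[i],
        hemisphere = label_table$hemisphere[i], metric = m,
        value = mean(vals, na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_table", "data.frame")
  out
}
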