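#' Long-format CSV round trip for item and score panels
#'
#' Item panels are written with columns `patient_id, arm, occasion, item,
#' value`; score panels with `patient_id, arm, occasion, score`. Missing
#' entries are written as empty fields.
#'
#' @param items a `qol_items` panel.
#' @param scores a `qol_scores` panel.
#' @param path CSV file path.
#' @return Writers return `path` invisibly; readers return the reconstructed
#'   panel object.
#' @export
write_item_panel <- function(items, path) {
  stopifnot(inherits(items, "qol_items"))
  d <- dim(items$responses)
  df <- data.frame(
    patient_id = rep(seq_len(d[1]), times = d[2] * d[3]),
    arm = rep(items$arm, times = d[2] * d[3]),
    occasion = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    item = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(items$responses))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_item_panel
#' @param n_categories J, needed to rebuild an item panel from CSV.
#' @export
read_item_panel <- function(path, n_categories) {
  df <- utils::read.csv(path)
  stopifnot(all(c("patient_id", "arm", "occasion", "item", "value") %in%
                  names(df)))
  n <- max(df$patient_id); tt <- max(df$occasion); I <- max(df$item)
  resp <- array(NA_integer_, dim = c(n, tt, I))
  resp[cbind(df$patient_id, df$occasion, df$item)] <- as.integer(df$value)
  arm <- integer(n)
  arm[df$patient_id] <- df$arm
  structure(list(responses = resp, arm = arm, n_categories = n_categories),
            class = "qol_items")
}

#' @rdname write_item_panel
#' @export
write_score_panel <- function(scores, path) {
  stopifnot(inherits(scores, "qol_scores"))
  df <- as_score_long(scores)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_item_panel
#' @export
read_score_panel <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("patient_id", "arm", "occasion", "score") %in% names(df)))
  n <- max(df$patient_id); tt <- max(df$occasion)
  sc <- matrix(NA_real_, n, tt)
  sc[cbind(df$patient_id, df$occasion)] <- df$score
  arm <- integer(n)
  arm[df$patient_id] <- df$arm
  structure(list(score = sc, arm = arm), class = "qol_scores")
}
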