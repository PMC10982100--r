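#' Write or read a pooled dataset as CSV
#'
#' Column layout: \code{group_id, route, dose, kin, tinf, time, replicate,
#' conc}; \code{kin}/\code{tinf} are empty for non-infusion groups.
#' Numeric values are written as full-precision decimals so a write/read
#' round trip reproduces the data frame exactly. Provenance metadata (a
#' list) is stored in a JSON sidecar \code{<path>.json}.
#'
#' @param data pooled data frame (or a \code{"pk_scenario"}, whose data
#'   and metadata are used).
#' @param path CSV file path.
#' @param metadata optional list written to the sidecar.
#' @return \code{read_pooled_csv} returns the data frame with the sidecar
#'   metadata (if present) in \code{attr(, "metadata")};
#'   \code{write_pooled_csv} returns \code{path} invisibly.
#' @export
write_pooled_csv <- function(data, path, metadata = list()) {
  if (inherits(data, "pk_scenario")) {
    metadata <- c(metadata,
                  list(scenario = data$name, model_id = data$oracle$model_id,
                       params = Filter(function(v) !is.na(v),
                                       unclass(data$oracle$params)),
                       cv = data$cv, n_rep = data$n_rep, seed = data$seed))
    data <- data$data
  }
  out <- data
  for (cl in c("dose", "kin", "tinf", "time", "conc"))
    out[[cl]] <- ifelse(is.na(data[[cl]]), "",
                        formatC(data[[cl]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (length(metadata))
    jsonlite::write_json(metadata, paste0(path, ".json"), digits = I(17),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pooled_csv
#' @export
read_pooled_csv <- function(path) {
  data <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(group_id = "character", route = "character",
                                   dose = "numeric", kin = "numeric",
                                   tinf = "numeric", time = "numeric",
                                   replicate = "integer", conc = "numeric")),
    error = function(e) stop(sprintf("malformed dataset file '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  need <- c("group_id", "route", "dose", "kin", "tinf", "time", "replicate", "conc")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop(sprintf("malformed dataset file '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  data <- validate_pooled_data(data)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(data, "metadata") <- jsonlite::read_json(side, simplifyVector = TRUE)
  data
}
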