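# Shared helpers for descriptor tables.
#
# A descriptor table is an ordinary tibble/data.frame: one compound ID column
# (default "compound_id"), one optional activity column (default "pIC50"),
# every other numeric column a descriptor.

#' Names of descriptor columns in a table
#'
#' @param data A descriptor table (data frame).
#' @param id Name of the compound-ID column.
#' @param activity Name of the activity column (ignored if absent).
#' @return Character vector of descriptor column names, in table order.
#' @export
descriptor_names <- function(data, id = "compound_id", activity = "pIC50") {
  setdiff(names(data), c(id, activity))
}

# Extract the numeric descriptor matrix (rows named by compound ID).
descriptor_matrix <- function(data, names = NULL, id = "compound_id",
                              activity = "pIC50") {
  if (is.null(names)) names <- descriptor_names(data, id, activity)
  missing <- setdiff(names, colnames(data))
  if (length(missing) > 0L) {
    abort(paste0("descriptor column(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "qsar_config_error")
  }
  x <- as.matrix(as.data.frame(data)[, names, drop = FALSE])
  if (!is.numeric(x)) {
    abort("descriptor columns must be numeric", class = "qsar_config_error")
  }
  if (id %in% colnames(data)) rownames(x) <- as.character(data[[id]])
  x
}

activity_vector <- function(data, activity = "pIC50") {
  if (!activity %in% colnames(data)) {
    abort(paste0("activity column '", activity, "' not found"),
          class = "qsar_config_error")
  }
  as.numeric(data[[activity]])
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(paste0("'", name, "' must be a single integer >= ", min),
          class = "qsar_config_error")
  }
  as.integer(x)
}
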