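#' Shannon diversity index
#'
#' Computes the Shannon diversity index \eqn{H = -\sum_i p_i \ln p_i} from a
#' vector of per-species abundances (stem counts), where
#' \eqn{p_i = n_i / \sum_j n_j}. Natural logarithm, so the result is in nats
#' and bounded by \eqn{\ln s} for \eqn{s} species.
#'
#' @param counts Numeric vector of positive per-species abundances.
#' @return Non-negative scalar, the Shannon index in nats.
#' @examples
#' shannon_index(c(5, 5))      # ln 2
#' shannon_index(c(1, 2, 3))
#' @export
shannon_index <- function(counts) {
  if (length(counts) == 0L) {
    stop_texdiv("'counts' must contain at least one species",
                class = "texdiv_validation_error")
  }
  if (!is.numeric(counts) || anyNA(counts) || any(counts <= 0)) {
    stop_texdiv("'counts' must be positive and free of NA",
                class = "texdiv_validation_error")
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Per-plot Shannon diversity from a species-count table
#'
#' Converts a long-format species-count table (one row per plot x species,
#' with a positive stem count) into one diversity record per plot: Shannon
#' index, species richness and total stem count. Plots absent from the table
#' are absent from the output.
#'
#' @param counts Data frame with columns `plot_id`, `species`, `count`.
#' @return Data frame with columns `plot_id`, `shannon`, `richness`,
#'   `total_stems`, one row per plot, ordered by `plot_id`. Summary
#'   statistics (`min`, `max`, `sd` of the Shannon index) are attached as the
#'   `"summary"` attribute.
#' @export
diversity_table <- function(counts) {
  req <- c("plot_id", "species", "count")
  if (!is.data.frame(counts) || !all(req %in% names(counts))) {
    stop_texdiv("'counts' must have columns plot_id, species, count",
                class = "texdiv_validation_error")
  }
  if (nrow(counts) == 0L) {
    out <- data.frame(plot_id = character(), shannon = numeric(),
                      richness = integer(), total_stems = numeric())
    attr(out, "summary") <- c(min = NA_real_, max = NA_real_, sd = NA_real_)
    return(out)
  }
  if (anyDuplicated(counts[, c("plot_id", "species")])) {
    stop_texdiv("duplicate (plot_id, species) rows",
                class = "texdiv_validation_error")
  }
  if (any(counts$count <= 0) || anyNA(counts$count)) {
    stop_texdiv("all counts must be >= 1",
                class = "texdiv_validation_error")
  }
  split_counts <- split(counts$count, counts$plot_id)
  out <- data.frame(
    plot_id     = names(split_counts),
    shannon     = vapply(split_counts, shannon_index, numeric(1)),
    richness    = vapply(split_counts, length, integer(1)),
    total_stems = vapply(split_counts, sum, numeric(1)),
    row.names   = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- c(min = min(out$shannon), max = max(out$shannon),
                            sd = stats::sd(out$shannon))
  out
}

#' Read/write species counts and diversity tables
#'
#' Thin CSV wrappers for the long-format species-count table
#' (`plot_id,species,count`) and the per-plot diversity table.
#'
#' @param path CSV file path.
#' @param x Data frame to write.
#' @return `read_species_counts` returns the validated count table;
#'   the writers return `path` invisibly.
#' @export
read_species_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plot_id", "species", "count")
  if (!all(req %in% names(x))) {
    stop_texdiv("species count CSV must have columns plot_id, species, count",
                class = "texdiv_validation_error")
  }
  x$plot_id <- as.character(x$plot_id)
  x
}

#' @rdname read_species_counts
#' @export
write_species_counts <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
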