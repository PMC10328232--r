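#' Implanted electrode with ordered contacts
#'
#' @param name electrode name (e.g. `"RA"`).
#' @param positions n x 3 matrix of contact positions, world-RAS mm, in
#'   physical order along the shaft (depth/strip) or row-major over the
#'   array (grid).
#' @param contacts optional character vector of contact labels; defaults to
#'   `"1".."n"`.
#' @param kind `"depth"`, `"grid"` or `"strip"`.
#' @param grid_shape integer `c(rows, cols)`; required for grids, where
#'   `rows * cols` must equal the contact count.
#' @param size optional contact size (diameter, mm), recycled; `NA` = unknown.
#' @export
electrode <- function(name, positions, contacts = NULL,
                      kind = c("depth", "grid", "strip"),
                      grid_shape = NULL, size = NA_real_) {
  kind <- match.arg(kind)
  positions <- as_points_matrix(positions)
  n <- nrow(positions)
  if (is.null(contacts)) contacts <- as.character(seq_len(n))
  if (length(contacts) != n) stop("one contact label per position required")
  if (anyDuplicated(contacts)) stop("duplicate contact labels in electrode ", name)
  if (kind == "grid") {
    if (is.null(grid_shape)) stop("grids require 'grid_shape'")
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 2L || prod(grid_shape) != n)
      stop(sprintf("grid_shape %s inconsistent with %d contacts",
                   paste(grid_shape, collapse = "x"), n))
  }
  structure(list(name = as.character(name), positions = positions,
                 contacts = as.character(contacts), kind = kind,
                 grid_shape = grid_shape,
                 size = rep_len(as.numeric(size), n)),
            class = "electrode")
}

#' @export
print.electrode <- function(x, ...) {
  cat(sprintf("<electrode %s> %s, %d contacts\n", x$name, x$kind,
              nrow(x$positions)))
  invisible(x)
}

#' Number of contacts
#' @param electrode an [electrode()].
#' @export
n_contacts <- function(electrode) nrow(electrode$positions)

# normalize "one electrode or list of electrodes" arguments
as_electrode_list <- function(x) {
  if (inherits(x, "electrode")) return(stats::setNames(list(x), x$name))
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "electrode")))
    stop("expected an electrode or a list of electrodes")
  stats::setNames(x, vapply(x, `[[`, "", "name"))
}
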