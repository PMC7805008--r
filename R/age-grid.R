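#' Five-year age grid with an open terminal group
#'
#' The demographic scaffold shared by every table in the pipeline: 5-year age
#' groups from 0 up to a terminal open-ended group (default 95+). All
#' population, employment and burden tables are indexed on this grid, and the
#' present-value sums over single years of age are mapped back onto it.
#'
#' @param group_starts integer vector of group lower bounds; must start at 0
#'   and be strictly increasing. Default `seq(0, 95, 5)`.
#' @return An object of class `age_grid`: a list with `starts`, `labels`
#'   (e.g. `"60-64"`, `"95+"`), `midpoints` (integer midpoint age used to
#'   assign a single age to deaths in a group), `width` and `n`.
#' @details The midpoint of a closed group \[x, x+w) is `x + floor(w/2)`
#'   (62 for 60-64). The terminal open group gets midpoint `start + 2`;
#'   under the default retirement horizon of 65 its present value is zero,
#'   so the choice is inert.
#' @export
age_grid <- function(group_starts = seq(0L, 95L, 5L)) {
  starts <- as.integer(group_starts)
  if (length(starts) < 2L) stop_validation("age grid needs at least two groups")
  if (starts[1L] != 0L) stop_validation("age grid must start at age 0")
  if (any(diff(starts) <= 0L)) stop_validation("age grid starts must be strictly increasing")
  n <- length(starts)
  width <- c(diff(starts), NA_integer_)
  labels <- c(
    paste0(starts[-n], "-", starts[-1L] - 1L),
    paste0(starts[n], "+")
  )
  midpoints <- c(starts[-n] + diff(starts) %/% 2L, starts[n] + 2L)
  structure(
    list(starts = starts, labels = labels, midpoints = midpoints,
         width = width, n = n),
    class = "age_grid"
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat("<age_grid> ", x$n, " groups: ", x$labels[1L], " ... ",
      x$labels[x$n], "\n", sep = "")
  invisible(x)
}

# Map single years of age to their group index on the grid.
age_to_group <- function(grid, age) {
  findInterval(age, grid$starts)
}

# Group label for each single age.
age_to_label <- function(grid, age) {
  grid$labels[age_to_group(grid, age)]
}
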