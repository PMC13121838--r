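## Dataset container and the flat index layout consumed by the sampler.
##
## Long-format tables:
##   responses: person, day, test, item, y, d
##   times:     person, day, test, seconds
## Days are integer indices per person; lapses (days between consecutive
## test dates) are supplied through the design, not inferred from a
## calendar.

#' Construct a DIR-RT dataset
#'
#' @param responses data.frame with columns `person`, `day`, `test`,
#'   `item`, `y` (binary), `d` (test-level target difficulty; constant
#'   within a `person`/`day`/`test` triple).
#' @param times data.frame with columns `person`, `day`, `test`, `seconds`
#'   (positive), one row per test, or `NULL` for the DIR (no response
#'   times) reduction.
#' @param design a [dirt_design]; its lapse structure must cover every
#'   observed `person`/`day`.
#' @return A `dirt_data` object.
#' @export
dirt_data <- function(responses, times = NULL, design) {
  need <- c("person", "day", "test", "item", "y", "d")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(responses$y %in% c(0, 1)))
  if (length(bad))
    stop("non-binary response y at responses row ", bad[1])
  key <- paste(responses$person, responses$day, responses$test,
               responses$item)
  if (anyDuplicated(key))
    stop("duplicate (person, day, test, item) key at responses row ",
         which(duplicated(key))[1])
  if (!is.null(times)) {
    needt <- c("person", "day", "test", "seconds")
    misst <- setdiff(needt, names(times))
    if (length(misst))
      stop("times table lacks column(s): ", paste(misst, collapse = ", "))
    bad <- which(!(times$seconds > 0))
    if (length(bad))
      stop("non-positive response time at times row ", bad[1])
    rk <- unique(paste(responses$person, responses$day, responses$test))
    tk <- paste(times$person, times$day, times$test)
    orphan <- which(!(tk %in% rk))
    if (length(orphan))
      stop("orphan time row (no matching test) at times row ", orphan[1])
    if (anyDuplicated(tk))
      stop("duplicate (person, day, test) key at times row ",
           which(duplicated(tk))[1])
    if (length(tk) != length(rk))
      stop("times table must cover every declared test (",
           length(tk), " of ", length(rk), " covered)")
  }
  obj <- structure(list(responses = responses, times = times,
                        design = design),
                   class = "dirt_data")
  invisible(flatten_data(obj))  # validates index consistency
  obj
}

#' Drop the response-time table
#'
#' Returns the identical dataset without its time table, selecting the DIR
#' (item responses only) model downstream.
#'
#' @param dataset a [dirt_data].
#' @return A `dirt_data` with `times = NULL`.
#' @export
make_dir_only_view <- function(dataset) {
  stopifnot(inherits(dataset, "dirt_data"))
  dirt_data(dataset$responses, NULL, dataset$design)
}

#' @export
print.dirt_data <- function(x, ...) {
  fl <- flatten_data(x)
  cat(sprintf("<dirt_data> %d persons, %d person-dates, %d tests, %d items%s\n",
              fl$n_persons, fl$n_cells, fl$n_tests, fl$n_items,
              if (fl$has_times) "" else " [DIR mode: no response times]"))
  invisible(x)
}

## Flat layout: cells = person-dates sorted by (person, day); tests sorted
## by (cell, test); items sorted by (test, item). Lapses come from the
## design and are capped at h_max.
flatten_data <- function(dataset) {
  ds <- dataset$design
  r <- dataset$responses
  ord <- order(r$person, r$day, r$test, r$item)
  r <- r[ord, , drop = FALSE]

  cell_key <- paste(r$person, r$day, sep = "\r")
  cells <- r[!duplicated(cell_key), c("person", "day")]
  cell_id <- match(cell_key, unique(cell_key))

  test_key <- paste(r$person, r$day, r$test, sep = "\r")
  tests <- r[!duplicated(test_key), c("person", "day", "test", "d")]
  test_id <- match(test_key, unique(test_key))

  dd <- r$d[!duplicated(test_key)]
  if (any(tapply(r$d, test_id, function(v) max(v) - min(v)) > 1e-9))
    stop("target difficulty d must be constant within a test")

  test_cell <- cell_id[!duplicated(test_key)]

  n_persons <- ds$n_persons
  if (any(!(r$person %in% seq_len(n_persons))))
    stop("person indices must lie in 1..n_persons of the design")

  # lapses per cell from the design: position of the day within the
  # person's date sequence
  cell_lapse <- numeric(nrow(cells))
  for (p in unique(cells$person)) {
    idx <- which(cells$person == p)
    days <- cells$day[idx]
    if (is.unsorted(days, strictly = TRUE))
      stop("duplicate or unsorted days for person ", p)
    pos <- seq_along(idx)
    lp <- ds$lapses[[p]]
    if (length(idx) > 1) {
      if (length(lp) < length(idx) - 1)
        stop("design lapse vector too short for person ", p)
      cell_lapse[idx] <- c(0, pmin(lp[pos[-length(pos)]], ds$h_max))
    } else cell_lapse[idx] <- 0
  }

  logT <- NULL
  has_times <- !is.null(dataset$times)
  if (has_times) {
    tm <- dataset$times
    tmk <- paste(tm$person, tm$day, tm$test, sep = "\r")
    pos <- match(paste(tests$person, tests$day, tests$test, sep = "\r"), tmk)
    logT <- log(tm$seconds[pos])
  }

  sp <- ds$subpop
  mu0 <- rep(ds$subpop_mu, length.out = max(sp))[sp]
  s0 <- rep(ds$subpop_sd, length.out = max(sp))[sp]

  list(n_persons = n_persons,
       n_cells = nrow(cells), n_tests = nrow(tests), n_items = nrow(r),
       cell_person = cells$person, cell_day = cells$day,
       cell_lapse = cell_lapse,
       test_cell = test_cell, d = dd, test_index = tests$test,
       has_times = has_times, logT = logT,
       item_test = test_id, y = r$y,
       sigma_b = ds$sigma_b, theta_M = ds$theta_M,
       mu0 = mu0, s0 = s0)
}

## 0-based copy for the C++ core
flat_for_cpp <- function(fl) {
  list(n_persons = fl$n_persons,
       cell_person = as.integer(fl$cell_person - 1L),
       cell_lapse = fl$cell_lapse,
       test_cell = as.integer(fl$test_cell - 1L),
       d = fl$d, has_times = fl$has_times,
       logT = if (fl$has_times) fl$logT else numeric(0),
       item_test = as.integer(fl$item_test - 1L),
       y = as.integer(fl$y),
       sigma_b = fl$sigma_b, theta_M = fl$theta_M,
       mu0 = fl$mu0, s0 = fl$s0)
}
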