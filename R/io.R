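## File formats: long-format CSV tables for responses, times and the
## design, JSON for configuration/manifests, CSV for posterior draws.
## All files are UTF-8, comma-separated, "." decimal.

#' Write a dataset to CSV tables
#'
#' Writes `<stem>_responses.csv` (person, day, test, item, y, d),
#' `<stem>_times.csv` (person, day, test, seconds; omitted in DIR mode)
#' and `<stem>_design.csv` (person, day, lapse plus the design constants
#' repeated on each row).
#'
#' @param dataset a [dirt_data].
#' @param stem path stem for the output files.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "dirt_data"))
  ds <- dataset$design
  files <- paste0(stem, "_responses.csv")
  write.csv(dataset$responses, files[1], row.names = FALSE)
  if (!is.null(dataset$times)) {
    f <- paste0(stem, "_times.csv")
    write.csv(dataset$times, f, row.names = FALSE)
    files <- c(files, f)
  }
  dd <- do.call(rbind, lapply(seq_len(ds$n_persons), function(p) {
    data.frame(person = p, day = seq_len(ds$n_dates),
               lapse = c(NA, ds$lapses[[p]]), subpop = ds$subpop[p])
  }))
  dd$sigma_b <- ds$sigma_b
  dd$theta_M <- ds$theta_M
  dd$h_max <- ds$h_max
  dd$subpop_mu <- rep(ds$subpop_mu, length.out = max(ds$subpop))[dd$subpop]
  dd$subpop_sd <- rep(ds$subpop_sd, length.out = max(ds$subpop))[dd$subpop]
  f <- paste0(stem, "_design.csv")
  write.csv(dd, f, row.names = FALSE)
  invisible(c(files, f))
}

#' Read a dataset from CSV tables
#'
#' Inverse of [write_dataset]. A missing/`NULL` times path yields the DIR
#' (no response times) dataset. Validation errors cite the offending row.
#'
#' @param responses_path CSV of item responses.
#' @param times_path CSV of test times, or `NULL`.
#' @param design_path CSV of the per-person day/lapse table with design
#'   constants.
#' @return A [dirt_data].
#' @export
read_dataset <- function(responses_path, times_path = NULL, design_path) {
  resp <- read.csv(responses_path)
  times <- if (!is.null(times_path) && file.exists(times_path))
    read.csv(times_path) else NULL
  dd <- read.csv(design_path)
  need <- c("person", "day", "lapse", "sigma_b", "theta_M", "h_max",
            "subpop", "subpop_mu", "subpop_sd")
  miss <- setdiff(need, names(dd))
  if (length(miss))
    stop("design table lacks column(s): ", paste(miss, collapse = ", "))
  np <- max(dd$person)
  lapses <- lapply(seq_len(np), function(p) {
    v <- dd$lapse[dd$person == p][-1]
    v
  })
  nd <- max(dd$day)
  sp <- vapply(seq_len(np), function(p) dd$subpop[dd$person == p][1], 0)
  smu <- vapply(sort(unique(sp)), function(j) dd$subpop_mu[dd$subpop == j][1], 0)
  ssd <- vapply(sort(unique(sp)), function(j) dd$subpop_sd[dd$subpop == j][1], 0)
  design <- dirt_design(np, nd,
                        tests_per_day = max(resp$test),
                        items_per_test = max(resp$item),
                        lapses = lapses, sigma_b = dd$sigma_b[1],
                        theta_M = dd$theta_M[1], h_max = dd$h_max[1],
                        subpop = as.integer(sp), subpop_mu = smu,
                        subpop_sd = ssd)
  dirt_data(resp, times, design)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run: seed, configuration echo,
#' input-file digests, package version and timestamp.
#'
#' @param path output JSON path.
#' @param cfg a [dirt_mcmc] (or any list).
#' @param inputs character vector of input file paths to digest.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, cfg, inputs = character(0)) {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, "")
  man <- list(seed = cfg$seed, config = unclass(cfg),
              inputs = as.list(digests),
              package_version = as.character(packageVersion("dirt")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(man)
}

#' Write posterior draws to CSV files
#'
#' One long-format file per parameter group: columns `iteration`, `index`
#' (cell or person where applicable) and `value`.
#'
#' @param fit a `dirt_fit`.
#' @param stem path stem.
#' @return Invisibly, the files written.
#' @export
write_draws <- function(fit, stem) {
  files <- character(0)
  for (g in names(fit$draws)) {
    dr <- fit$draws[[g]]
    df <- if (is.matrix(dr)) {
      data.frame(iteration = rep(seq_len(nrow(dr)), ncol(dr)),
                 index = rep(seq_len(ncol(dr)), each = nrow(dr)),
                 value = as.vector(dr))
    } else {
      data.frame(iteration = seq_along(dr), index = 1L, value = dr)
    }
    f <- paste0(stem, "_", g, ".csv")
    write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
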