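#' Write and read outline tables
#'
#' Outlines are exchanged as long-format CSV with columns
#' `specimen_id`, `point`, `x`, `y`.
#'
#' @param outlines list of [outline]s.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_outlines_csv <- function(outlines, path) {
  tabs <- lapply(outlines, function(o)
    data.frame(specimen_id = o$specimen_id,
               point = seq_len(nrow(o$points)),
               x = o$points[, 1L], y = o$points[, 2L]))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outlines_csv
#' @return `read_outlines_csv`: named list of [outline]s.
#' @export
read_outlines_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("specimen_id", "point", "x", "y") %in% names(tab)))
  out <- lapply(split(tab, tab$specimen_id), function(d) {
    d <- d[order(d$point), ]
    outline(cbind(d$x, d$y), d$specimen_id[1L])
  })
  out[unique(tab$specimen_id)]
}

#' Write and read calibration curves
#'
#' Three-column CSV in the conventional calibration-curve layout:
#' `calBP`, `c14BP`, `error` (here in ka).
#'
#' @param curve a [cal_curve].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_calcurve_csv <- function(curve, path) {
  utils::write.csv(data.frame(calBP = curve$grid, c14BP = curve$c14_mean,
                              error = curve$c14_error),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calcurve_csv
#' @return `read_calcurve_csv`: a [cal_curve].
#' @export
read_calcurve_csv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(ncol(tab) >= 3L)
  cal_curve(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Write and read per-locale radiocarbon date tables
#'
#' CSV with columns `locale_id`, `lab_id`, `c14_age`, `error`.
#'
#' @param c14_tables named list (by locale) of data.frames with
#'   `c14_age` and `error` columns.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_dates_csv <- function(c14_tables, path) {
  rows <- lapply(names(c14_tables), function(loc) {
    d <- c14_tables[[loc]]
    if (!nrow(d)) return(NULL)
    data.frame(locale_id = loc,
               lab_id = sprintf("%s_%d", loc, seq_len(nrow(d))),
               c14_age = d$c14_age, error = d$error)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dates_csv
#' @return `read_dates_csv`: named list of per-locale date tables.
#' @export
read_dates_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$locale_id),
         function(d) data.frame(c14_age = d$c14_age, error = d$error))
}

#' Write a trait matrix as TSV
#'
#' @param traits a [trait_matrix].
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_traits_tsv <- function(traits, path) {
  tab <- data.frame(taxon_id = traits$taxa, traits$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_tsv
#' @return `read_traits_tsv`: a [trait_matrix].
#' @export
read_traits_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  trait_matrix(as.matrix(tab[, -1L, drop = FALSE]), taxa = tab[[1L]])
}
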