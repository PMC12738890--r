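#' Write a genotype tibble as a STRUCTURE input file
#'
#' Two-rows-per-individual flat text: individual ID, 1-based population index,
#' then one column per locus holding one allele of the genotype per row.
#' Missing alleles are written as -9 (the STRUCTURE convention). A header line
#' with the locus names is included.
#'
#' @param data genotype tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(data, path) {
  locs <- loci(data)
  wide <- data |>
    dplyr::arrange(.data$population, .data$individual, .data$locus)
  ids <- unique(wide$individual)
  nl <- length(locs)
  a1 <- matrix(wide$allele_1, nrow = nl)
  a2 <- matrix(wide$allele_2, nrow = nl)
  pop_idx <- as.integer(wide$population[seq(1L, by = nl, length.out = length(ids))])
  fmt <- function(x) ifelse(is.na(x), "-9", as.character(x))
  rows <- character(2L * length(ids))
  for (i in seq_along(ids)) {
    rows[2L * i - 1L] <- paste(c(ids[i], pop_idx[i], fmt(a1[, i])), collapse = "\t")
    rows[2L * i]     <- paste(c(ids[i], pop_idx[i], fmt(a2[, i])), collapse = "\t")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(locs, collapse = "\t"), con)
  writeLines(rows, con)
  invisible(path)
}

#' Read back a STRUCTURE file written by [write_structure()]
#'
#' Used for round-trip checks; population labels are recovered as the 1-based
#' index written out (the STRUCTURE format stores no label strings).
#'
#' @param data_labels optional character vector mapping population index to
#'   label; defaults to the index as character.
#' @param path path to the file.
#' @return a genotype tibble.
#' @export
read_structure <- function(path, data_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  locs <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (length(body) %% 2L != 0L) abort("STRUCTURE file must have two rows per individual")
  cells <- lapply(body, function(x) strsplit(x, "\t", fixed = TRUE)[[1]])
  odd <- cells[seq(1L, length(cells), by = 2L)]
  even <- cells[seq(2L, length(cells), by = 2L)]
  ids <- vapply(odd, `[[`, character(1), 1L)
  pop_idx <- as.integer(vapply(odd, `[[`, character(1), 2L))
  if (is.null(data_labels)) data_labels <- as.character(sort(unique(pop_idx)))
  to_int <- function(rows) {
    m <- t(vapply(rows, function(r) as.integer(r[-(1:2)]), integer(length(locs))))
    m[m == -9L] <- NA_integer_
    m
  }
  m1 <- to_int(odd)
  m2 <- to_int(even)
  nl <- length(locs)
  genotype_tibble(
    individual = rep(ids, each = nl),
    population = rep(data_labels[pop_idx], each = nl),
    locus = rep(locs, times = length(ids)),
    allele_1 = as.vector(t(m1)),
    allele_2 = as.vector(t(m2)),
    pop_levels = data_labels[sort(unique(pop_idx))],
    locus_levels = locs
  )
}
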