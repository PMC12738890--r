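#' Read a GenAlEx-dialect codominant SSR table
#'
#' Reads the comma-separated GenAlEx layout for codominant data: exactly two
#' header rows, then one data row per individual. The counts row declares the
#' locus count, total sample count, number of populations and each population's
#' size; the labels row names the individual and population columns followed by
#' one locus name per pair of allele columns. Allele states are fragment sizes
#' in nucleotides; the missing-data code (default `"0"`) maps to `NA`.
#'
#' @param path path to the CSV file.
#' @param missing_code string coding a missing allele (default `"0"`).
#' @return a genotype tibble (see [genotype_tibble()]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' d <- genotype_tibble(c("i1", "i1"), c("A", "A"), c("L1", "L2"),
#'                      c(180L, 200L), c(182L, 200L))
#' write_genalex(d, f)
#' read_genalex(f)
read_genalex <- function(path, missing_code = "0") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort("malformed GenAlEx file: need 2 header rows plus data (line 1)")
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  counts <- split_csv(lines[1])
  counts_num <- suppressWarnings(as.integer(counts))
  if (length(counts_num) < 4L || any(is.na(counts_num[1:3]))) {
    abort("malformed GenAlEx header: counts row must be n_loci,n_samples,n_pops,sizes... (line 1)")
  }
  n_loci <- counts_num[1]
  n_samples <- counts_num[2]
  n_pops <- counts_num[3]
  pop_sizes <- counts_num[4:(3 + n_pops)]
  if (anyNA(pop_sizes) || length(pop_sizes) < n_pops) {
    abort("malformed GenAlEx header: fewer population sizes than declared populations (line 1)")
  }
  labels <- split_csv(lines[2])
  # strsplit drops trailing empty fields; pad to the declared width
  if (length(labels) < 2L + 2L * n_loci) {
    labels <- c(labels, rep("", 2L + 2L * n_loci - length(labels)))
  }
  allele_cols <- length(labels) - 2L
  if (allele_cols < 2L || allele_cols %% 2L != 0L) {
    abort("malformed GenAlEx header: odd number of allele columns (line 2)")
  }
  locus_names <- labels[seq(3L, length(labels), by = 2L)]
  locus_names <- locus_names[locus_names != ""]
  if (length(locus_names) != n_loci) {
    abort(paste0("malformed GenAlEx header: ", length(locus_names),
                 " locus labels but counts row declares ", n_loci, " (line 2)"))
  }
  body <- lines[-(1:2)]
  body <- body[trimws(body) != ""]
  if (length(body) != n_samples) {
    abort(paste0("GenAlEx body has ", length(body), " rows but header declares ",
                 n_samples, " samples"))
  }
  cells <- lapply(body, split_csv)
  widths <- vapply(cells, length, integer(1))
  if (any(widths < 2L + 2L * n_loci)) {
    abort(paste0("malformed GenAlEx data row (line ",
                 which(widths < 2L + 2L * n_loci)[1] + 2L, "): too few columns"))
  }
  ind <- vapply(cells, `[[`, character(1), 1L)
  pop <- vapply(cells, `[[`, character(1), 2L)
  allele_mat <- t(vapply(cells, function(r) {
    a <- r[3:(2 + 2L * n_loci)]
    a[trimws(a) == missing_code | trimws(a) == ""] <- NA_character_
    as.integer(a)
  }, integer(2L * n_loci)))

  # population blocks must match the declared sizes
  pop_rle <- rle(pop)
  if (length(pop_rle$values) != n_pops || !all(pop_rle$lengths == pop_sizes)) {
    abort(paste0("population blocks (",
                 paste(pop_rle$lengths, collapse = ","),
                 ") do not match declared sizes (",
                 paste(pop_sizes, collapse = ","), ")"))
  }

  genotype_tibble(
    individual = rep(ind, each = n_loci),
    population = rep(pop, each = n_loci),
    locus = rep(locus_names, times = n_samples),
    allele_1 = as.vector(t(allele_mat[, 2L * seq_len(n_loci) - 1L, drop = FALSE])),
    allele_2 = as.vector(t(allele_mat[, 2L * seq_len(n_loci), drop = FALSE])),
    pop_levels = pop_rle$values,
    locus_levels = locus_names
  )
}

#' Write a genotype tibble in the GenAlEx dialect
#'
#' Inverse of [read_genalex()]: two header rows followed by one comma-separated
#' row per individual with two allele columns per locus. Missing genotypes are
#' written as the missing code on both columns. `read_genalex(write_genalex(x))`
#' is the identity on allele content and population assignment.
#'
#' @param data genotype tibble.
#' @param path output path.
#' @param missing_code string to write for a missing allele (default `"0"`).
#' @return `path`, invisibly.
#' @export
write_genalex <- function(data, path, missing_code = "0") {
  locs <- loci(data)
  pops <- populations(data)
  sizes <- population_sizes(data)$n
  wide <- data |>
    dplyr::arrange(.data$population, .data$individual, .data$locus)
  ids <- unique(wide$individual)
  n <- length(ids)
  a1 <- matrix(wide$allele_1, nrow = length(locs))
  a2 <- matrix(wide$allele_2, nrow = length(locs))
  fmt <- function(x) ifelse(is.na(x), missing_code, as.character(x))
  rows <- vapply(seq_len(n), function(i) {
    geno <- as.vector(rbind(fmt(a1[, i]), fmt(a2[, i])))
    paste(c(ids[i], as.character(wide$population[(i - 1L) * length(locs) + 1L]), geno),
          collapse = ",")
  }, character(1))
  header1 <- paste(c(length(locs), n, length(pops), sizes), collapse = ",")
  header2 <- paste(c("Individual", "Population",
                     as.vector(rbind(locs, rep("", length(locs))))), collapse = ",")
  writeLines(c(header1, header2, rows), path)
  invisible(path)
}
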