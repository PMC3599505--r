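#' Read a SNP-array probe table
#'
#' Reads the tab-delimited probe layout of Illumina "final report" /
#' PennCNV-style files: a header row and columns `Name`, `Chr`, `Position`,
#' `LRR`, `BAF` (matched case-insensitively, with `Log R Ratio` / `B Allele
#' Freq` accepted as aliases). Empty fields and `NA` become missing values.
#' Rows are grouped by chromosome and sorted by position; duplicated
#' positions on a chromosome are an error, unsorted input is sorted with a
#' warning.
#'
#' @param path Path to the tab-delimited file.
#' @return Tibble with columns `probe_id`, `chrom`, `position`, `lrr`, `baf`,
#'   sorted by `(chrom, position)`.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  nm <- tolower(gsub("[ ._]", "", names(raw)))
  pick <- function(aliases, col) {
    hit <- which(nm %in% aliases)
    if (!length(hit)) abort(paste0("probe table lacks a '", col, "' column"))
    raw[[hit[1]]]
  }
  probes <- tibble::tibble(
    probe_id = pick(c("name", "probeid", "snpname"), "Name"),
    chrom = pick(c("chr", "chrom", "chromosome"), "Chr"),
    position = pick(c("position", "pos"), "Position"),
    lrr = pick(c("lrr", "logrratio"), "LRR"),
    baf = pick(c("baf", "ballelefreq", "ballelefrequency"), "BAF"))

  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      abort(paste0("non-numeric ", col, " at line(s): ",
                   paste(utils::head(bad + 1L, 5), collapse = ", ")))
    out
  }
  probes$position <- num(probes$position, "Position")
  probes$lrr <- num(probes$lrr, "LRR")
  probes$baf <- num(probes$baf, "BAF")
  if (anyNA(probes$position)) abort("missing probe positions")

  dup <- probes |>
    dplyr::group_by(.data$chrom, .data$position) |>
    dplyr::filter(dplyr::n() > 1)
  if (nrow(dup))
    abort(paste0("duplicated positions: ",
                 paste(utils::head(dup$probe_id, 10), collapse = ", ")))
  sorted <- probes |> dplyr::arrange(.data$chrom, .data$position)
  if (!identical(sorted$probe_id, probes$probe_id))
    warn("probe table was not sorted by (chrom, position); sorting")
  sorted
}

#' Write a probe table
#'
#' Writes probes in the same tab-delimited layout [read_probe_table()] reads
#' (`Name`, `Chr`, `Position`, `LRR`, `BAF`; missing as `NA`).
#'
#' @param probes Tibble with `probe_id`, `chrom`, `position`, `lrr`, `baf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  out <- tibble::tibble(Name = probes$probe_id, Chr = probes$chrom,
                        Position = probes$position, LRR = probes$lrr,
                        BAF = probes$baf)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a ground-truth profile
#'
#' Writes a BED-like tab-delimited truth table (chrom, 0-based half-open
#' probe range, copy number, B-allele count, LOH type) and, next to it, a
#' `<path>.changepoints` file listing the true change-point indices.
#'
#' @param profile A `cnv_profile`.
#' @param path Output path for the region table.
#' @param chrom Chromosome label. Default `"1"`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(profile, path, chrom = "1") {
  pr <- profile$probes
  run <- cumsum(c(TRUE, pr$copy_number[-1] != pr$copy_number[-nrow(pr)] |
                        pr$n_b_alleles[-1] != pr$n_b_alleles[-nrow(pr)]))
  regions <- pr |>
    dplyr::mutate(run = run) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom = chrom, start_probe = min(.data$index),
                     end_probe = max(.data$index) + 1L,
                     copy_number = .data$copy_number[1],
                     n_b_alleles = .data$n_b_alleles[1],
                     loh_type = .data$loh_type[1], .groups = "drop") |>
    dplyr::select(!"run")
  readr::write_tsv(regions, path, progress = FALSE)
  writeLines(as.character(profile$changepoints),
             paste0(path, ".changepoints"))
  invisible(path)
}

#' Write segmentation results
#'
#' Writes the segment table produced by [segment_profile()] as tab-delimited
#' text, plus a `<path>.changepoints` file with one `chrom<TAB>index` row per
#' interior change-point. Probe index ranges are 0-based half-open; genomic
#' positions are the 1-based positions of the first and last probe of each
#' segment.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(segments, path, progress = FALSE)
  cps <- segments |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(.data$start > 0) |>
    dplyr::select("chrom", index = "start")
  readr::write_tsv(cps, paste0(path, ".changepoints"), progress = FALSE)
  invisible(path)
}
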