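#' Read / write hallmark gene lists as plain-text files
#'
#' Each list is one text file (one gene symbol per line) named
#' `<kind>__<name>.txt` with `kind` either `multi` or `individual`; the
#' optional `control_set.txt` holds the fixed control genes. This mirrors
#' how curated senescence lists (SenMayo, Fridman senescence-up, consortium
#' lists, individual hallmark programs) are usually shipped.
#'
#' @param hallmarks A `hallmark_sets` object.
#' @param dir Directory to write to / read from.
#' @return `write_hallmark_sets()` returns `dir` invisibly;
#'   `read_hallmark_sets()` returns a `hallmark_sets` object. If no control
#'   set file is present, the control pool/set must be rebuilt against a
#'   dataset's gene universe with [with_control_set()].
#' @export
write_hallmark_sets <- function(hallmarks, dir) {
  stopifnot(inherits(hallmarks, "hallmark_sets"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(hallmarks$multi)) {
    writeLines(hallmarks$multi[[nm]],
               file.path(dir, paste0("multi__", nm, ".txt")))
  }
  for (nm in names(hallmarks$individual)) {
    writeLines(hallmarks$individual[[nm]],
               file.path(dir, paste0("individual__", nm, ".txt")))
  }
  if (length(hallmarks$control_set)) {
    writeLines(hallmarks$control_set, file.path(dir, "control_set.txt"))
  }
  invisible(dir)
}

#' @rdname write_hallmark_sets
#' @export
read_hallmark_sets <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no .txt gene lists found in '%s'", dir))
  multi <- list(); individual <- list(); control_set <- character()
  for (f in files) {
    base <- sub("\\.txt$", "", basename(f))
    genes <- readLines(f)
    genes <- genes[nzchar(genes)]
    if (base == "control_set") {
      control_set <- genes
    } else if (startsWith(base, "multi__")) {
      multi[[sub("^multi__", "", base)]] <- genes
    } else if (startsWith(base, "individual__")) {
      individual[[sub("^individual__", "", base)]] <- genes
    } else {
      individual[[base]] <- genes  # bare files default to individual lists
    }
  }
  structure(list(multi = multi, individual = individual,
                 control_pool = character(), control_set = control_set),
            class = "hallmark_sets")
}

#' Attach a control pool / fixed control set to hallmark lists
#'
#' Rebuilds the control pool as all genes of `universe` outside every list,
#' and (re)samples the fixed control set of size `control_n` from it.
#'
#' @param hallmarks A `hallmark_sets` object.
#' @param universe Character vector of all genes in the dataset.
#' @param control_n Fixed control set size (default 2000; if the pool is
#'   smaller, all of it is used, with a log).
#' @param seed Sampling seed.
#' @return The updated `hallmark_sets`.
#' @export
with_control_set <- function(hallmarks, universe, control_n = 2000,
                             seed = 1L) {
  stopifnot(inherits(hallmarks, "hallmark_sets"))
  listed <- unique(c(unlist(hallmarks$multi), unlist(hallmarks$individual)))
  pool <- setdiff(universe, listed)
  if (length(pool) < control_n) {
    inform(sprintf("with_control_set: pool has only %d genes; using all",
                   length(pool)))
    cs <- pool
  } else {
    cs <- with_seed(seed, sample(pool, control_n))
  }
  hallmarks$control_pool <- pool
  hallmarks$control_set <- cs
  hallmarks
}
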