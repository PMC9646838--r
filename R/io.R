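# Cohort manifest handling, stratified splitting, and slide-map
# serialisation. Manifests are UTF-8 TSV files with a header row and empty
# strings for missing values; all writes go through a temp-file-then-rename
# so a crash never leaves a half-written file behind.

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

manifest_splits <- c("train", "val", "test")

#' Read and validate a cohort manifest
#'
#' Expected columns: `slide_id` (required, unique), and optionally `path`,
#' `label`, `time`, `event`, `split`, `n_patches`. `time` and `event` must
#' be present or absent together per row; `split` values must be one of
#' `train`, `val`, `test`. Validation errors cite the offending data row.
#'
#' @param path TSV file with a header row.
#' @return the manifest data frame, row order preserved.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  if (!"slide_id" %in% names(m)) stop("manifest lacks a slide_id column")
  dup <- which(duplicated(m$slide_id))
  if (length(dup))
    stop("duplicate slide_id '", m$slide_id[dup[1]], "' at row ", dup[1])
  if ("split" %in% names(m)) {
    bad <- which(!is.na(m$split) & !m$split %in% manifest_splits)
    if (length(bad))
      stop("unknown split '", m$split[bad[1]], "' at row ", bad[1])
  }
  has_time <- if ("time" %in% names(m)) !is.na(m$time) else rep(FALSE, nrow(m))
  has_event <- if ("event" %in% names(m)) !is.na(m$event) else rep(FALSE, nrow(m))
  orphan <- which(xor(has_time, has_event))
  if (length(orphan))
    stop("time/event must be present together; offending row ", orphan[1])
  invisible(m)
}

#' Write a manifest TSV
#'
#' @param manifest data frame with at least `slide_id`.
#' @param path output path; written atomically.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  atomic_write(function(tmp)
    utils::write.table(manifest, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ""),
    path)
}

#' Stratified split of a manifest
#'
#' Allocates slides to the named splits proportionally within each stratum.
#' Each stratum first receives `floor(fraction * n)` slides per split; the
#' remainder is assigned in order of the largest fractional part (ties by
#' split order), and membership is randomised by `seed`.
#'
#' @param manifest a manifest data frame.
#' @param fractions named numeric vector summing to 1, names from
#'   `train`/`val`/`test` (e.g. `c(train = 0.75, test = 0.25)`).
#' @param seed integer seed.
#' @param by stratification column (default `label`; slides with `NA` form
#'   their own stratum).
#' @return the manifest with a `split` column filled in.
#' @export
stratified_split <- function(manifest, fractions = c(train = 0.75, test = 0.25),
                             seed = 1L, by = "label") {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions)) || !all(names(fractions) %in% manifest_splits))
    stop("fractions must be named with train/val/test")
  strata <- if (by %in% names(manifest)) as.character(manifest[[by]])
            else rep("all", nrow(manifest))
  strata[is.na(strata)] <- "<na>"
  set.seed(as.integer(seed))
  split <- character(nrow(manifest))
  for (g in unique(strata)) {
    rows <- which(strata == g)
    n <- length(rows)
    if (n < length(fractions))
      stop("stratum '", g, "' has ", n, " slides but ", length(fractions),
           " splits were requested")
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(-(fractions * n - base))[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    rows <- rows[sample.int(n)]
    split[rows] <- rep(names(fractions), base)
  }
  manifest$split <- split
  manifest
}

#' Persist a slide map
#'
#' Writes the `K x (H*W)` matrix as a TSV, a JSON sidecar with provenance
#' (`slide_id`, `K`, `H`, `W`, `pad_count`, per-row patch indices), and an
#' 8-bit PNG heatmap scaled to the matrix range for quick inspection.
#'
#' @param map an `hm_hipomap`.
#' @param stem output path stem; writes `stem.tsv`, `stem.json`, `stem.png`.
#' @return `stem`, invisibly.
#' @export
write_hipomap <- function(map, stem) {
  stopifnot(inherits(map, "hm_hipomap"))
  atomic_write(function(tmp)
    utils::write.table(map$X, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE),
    paste0(stem, ".tsv"))
  atomic_write(function(tmp)
    jsonlite::write_json(list(slide_id = map$slide_id, K = map$K,
                              H = map$H, W = map$W, pad_count = map$pad_count,
                              patch_index = map$patch_index),
                         tmp, auto_unbox = TRUE, na = "null", digits = NA),
    paste0(stem, ".json"))
  rng <- range(map$X)
  img <- if (diff(rng) > 0) (map$X - rng[1]) / diff(rng) else map$X * 0
  atomic_write(function(tmp) png::writePNG(img, tmp), paste0(stem, ".png"))
  invisible(stem)
}

#' @rdname write_hipomap
#' @export
read_hipomap <- function(stem) {
  x <- as.matrix(utils::read.delim(paste0(stem, ".tsv"), header = FALSE,
                                   sep = "\t"))
  dimnames(x) <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(X = x, K = nrow(x),
                 H = meta$H %||% NA_integer_, W = meta$W %||% NA_integer_,
                 pad_count = meta$pad_count,
                 patch_index = as.integer(meta$patch_index),
                 slide_id = meta$slide_id),
            class = "hm_hipomap")
}

#' @export
print.hm_hipomap <- function(x, ...) {
  cat(sprintf("<hm_hipomap> %s: %d x %d (pad %d)\n",
              x$slide_id %||% "?", nrow(x$X), ncol(x$X), x$pad_count))
  invisible(x)
}

#' @export
print.hm_slide <- function(x, ...) {
  cat(sprintf("<hm_slide> %s: %d patches, label %s\n", x$slide_id,
              length(x$patches), format(x$label %||% NA)))
  invisible(x)
}
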