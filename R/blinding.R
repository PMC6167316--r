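#' Blind a folder of images for unbiased scoring
#'
#' Duplicates every image of `in_dir` into `out_dir` under a random
#' six-digit code (extension preserved so images stay openable) and
#' writes a key table mapping original to coded names.  Originals are
#' never modified.  With a seed the codes are reproducible; without one
#' the codes are entropy-seeded, as blinding demands in practice.
#'
#' @param in_dir Directory of images (TIFF/PNG; other files are skipped
#'   with a warning).
#' @param out_dir Output directory (created if missing; must differ from
#'   `in_dir`).
#' @param seed Optional integer seed for reproducible codes.
#' @param key_file Path of the key CSV (header `original_name,code_name`);
#'   default `blinding_key.csv` inside `out_dir`.
#' @return The key as a data.frame with columns `original_name`,
#'   `code_name`, invisibly.
#' @seealso [unblind_table()]
#' @export
blind_folder <- function(in_dir, out_dir, seed = NULL,
                         key_file = file.path(out_dir, "blinding_key.csv")) {
  if (!dir.exists(in_dir)) stop("in_dir not found: ", in_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (normalizePath(in_dir) == normalizePath(out_dir))
    stop("out_dir must differ from in_dir", call. = FALSE)
  files <- list.files(in_dir)
  is_img <- grepl("\\.(tif|tiff|png)$", files, ignore.case = TRUE)
  if (any(!is_img))
    warning("skipping non-image file(s): ",
            paste(files[!is_img], collapse = ", "))
  files <- files[is_img]
  if (!length(files)) stop("no images in ", in_dir, call. = FALSE)

  codes <- with_seed(seed, {
    out <- character(length(files))
    used <- character(0)
    for (i in seq_along(files)) {
      for (attempt in 1:1000) {
        cand <- sprintf("%06d", sample.int(1000000L, 1L) - 1L)
        if (!cand %in% used) break
        if (attempt == 1000)
          stop("could not draw a collision-free code in 1000 attempts",
               call. = FALSE)
      }
      used <- c(used, cand)
      out[i] <- cand
    }
    out
  })
  code_names <- paste0(codes, ".", tools::file_ext(files))
  ok <- file.copy(file.path(in_dir, files), file.path(out_dir, code_names),
                  overwrite = FALSE)
  if (!all(ok)) stop("failed to copy some images", call. = FALSE)
  key <- data.frame(original_name = files, code_name = code_names,
                    stringsAsFactors = FALSE)
  utils::write.csv(key, key_file, row.names = FALSE)
  invisible(key)
}

#' Read a blinding key
#'
#' @param path Key CSV written by [blind_folder()].
#' @return Data.frame with columns `original_name`, `code_name`.
#' @export
read_blinding_key <- function(path) {
  key <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("original_name", "code_name") %in% names(key)))
    stop("key CSV must have columns original_name,code_name",
         call. = FALSE)
  if (anyDuplicated(key$code_name) || anyDuplicated(key$original_name))
    stop("blinding key is not bijective", call. = FALSE)
  key
}

#' Re-attach original image names to a coded result table
#'
#' Maps the `image_id` column of a result table from coded names back to
#' the originals using the key; values are untouched.  Codes may appear
#' with or without their file extension.
#'
#' @param results A result table keyed by coded names.
#' @param key A blinding key (data.frame from [blind_folder()] or
#'   [read_blinding_key()]).
#' @return The result table keyed by original names.
#' @export
unblind_table <- function(results, key) {
  stopifnot("image_id" %in% names(results),
            all(c("original_name", "code_name") %in% names(key)))
  idx <- match(results$image_id, key$code_name)
  bare <- is.na(idx)
  idx[bare] <- match(results$image_id[bare],
                     tools::file_path_sans_ext(key$code_name))
  if (anyNA(idx))
    stop("code(s) not in the blinding key: ",
         paste(unique(results$image_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  results$image_id <- key$original_name[idx]
  results
}
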