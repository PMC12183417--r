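# HDF5 input/output through the environment's Python h5py (there is no R
# HDF5 binding in this stack). Complex datasets cross the process boundary
# as raw float64 binaries with a JSON shape header; see
# inst/python/h5bridge.py.

find_python <- function() {
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (required for HDF5 I/O)")
}

bridge_path <- function()
  system.file("python", "h5bridge.py", package = "pirecon", mustWork = TRUE)

run_bridge <- function(args) {
  out <- suppressWarnings(
    system2(find_python(), c(shQuote(bridge_path()), args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 bridge failed: ", paste(out, collapse = " "))
  invisible(out)
}

# read a complex dataset as an R array (same axis order as on disk)
h5_read_complex <- function(path, dataset) {
  binfile <- tempfile(fileext = ".bin"); metafile <- tempfile(fileext = ".json")
  on.exit(unlink(c(binfile, metafile)), add = TRUE)
  run_bridge(c("read", shQuote(path), shQuote(dataset),
               shQuote(binfile), shQuote(metafile)))
  meta <- jsonlite::fromJSON(metafile)
  shape <- as.integer(meta$shape)
  raw <- readBin(binfile, "double", n = 2L * prod(shape))
  z <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  # C-order on disk -> fill reversed dims, then permute back
  dim(z) <- rev(shape)
  arr <- aperm(z, rev(seq_along(shape)))
  attr(arr, "h5attrs") <- meta$attrs
  arr
}

# write a complex array (axis order preserved on disk)
h5_write_complex <- function(path, dataset, arr, attrs = NULL) {
  if (!is.complex(arr)) storage.mode(arr) <- "complex"
  binfile <- tempfile(fileext = ".bin"); metafile <- tempfile(fileext = ".json")
  on.exit(unlink(c(binfile, metafile)), add = TRUE)
  v <- as.vector(aperm(arr, rev(seq_along(dim(arr)))))   # C order
  writeBin(as.double(rbind(Re(v), Im(v))), binfile)
  meta <- list(shape = dim(arr))
  if (!is.null(attrs) && length(attrs)) meta$attrs <- attrs
  jsonlite::write_json(meta, metafile, auto_unbox = FALSE, digits = NA)
  run_bridge(c("write", shQuote(path), shQuote(dataset),
               shQuote(binfile), shQuote(metafile)))
  invisible(path)
}

#' Read a fastMRI-dialect multi-coil HDF5 file
#'
#' Expects a complex `kspace` dataset with layout `[slice, coil, kx, ky]`
#' and materializes one [mc_kspace] per slice. Files lacking the dataset or
#' holding a non-complex dtype are rejected with a format error.
#'
#' @param path HDF5 file path.
#' @param dataset dataset name (default `"kspace"`).
#' @return list of [mc_kspace] objects, one per slice.
#' @export
read_fastmri_h5 <- function(path, dataset = "kspace") {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- h5_read_complex(path, dataset)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D [slice, coil, kx, ky] dataset, got ",
         length(dim(arr)), "-D")
  lapply(seq_len(dim(arr)[1]), function(s)
    mc_kspace(array(arr[s, , , ], dim(arr)[2:4])))
}

#' Write multi-coil k-space slices in the fastMRI HDF5 dialect
#'
#' @param path output HDF5 file (overwritten).
#' @param slices list of [mc_kspace] objects with identical dimensions.
#' @param dataset dataset name (default `"kspace"`).
#' @return the path, invisibly.
#' @export
write_fastmri_h5 <- function(path, slices, dataset = "kspace") {
  if (inherits(slices, "mc_kspace")) slices <- list(slices)
  d <- dim(slices[[1]]$data)
  arr <- array(0i, c(length(slices), d))
  for (s in seq_along(slices)) {
    stopifnot(identical(dim(slices[[s]]$data), d))
    arr[s, , , ] <- slices[[s]]$data
  }
  if (file.exists(path)) unlink(path)
  h5_write_complex(path, dataset, arr)
}

#' Write a simulated acquisition to the package's internal HDF5 container
#'
#' Datasets: `kspace` (complex, `[echo, coil, kx, ky]`) and optionally
#' `acs` (complex, `[coil, kx, ky]` with attributes `mode`, `ky_origin`);
#' `kspace` carries attributes `echo_times_ms` and `seed`.
#'
#' @param path output HDF5 file (overwritten).
#' @param echoes list of fully sampled [mc_kspace], one per echo.
#' @param acs optional [acs_block].
#' @param echo_times_ms,seed acquisition metadata stored as attributes.
#' @return the path, invisibly.
#' @export
write_sim_h5 <- function(path, echoes, acs = NULL,
                         echo_times_ms = numeric(0), seed = 0L) {
  if (inherits(echoes, "mc_kspace")) echoes <- list(echoes)
  d <- dim(echoes[[1]]$data)
  arr <- array(0i, c(length(echoes), d))
  for (e in seq_along(echoes)) arr[e, , , ] <- echoes[[e]]$data
  if (file.exists(path)) unlink(path)
  h5_write_complex(path, "kspace", arr,
                   attrs = list(echo_times_ms = echo_times_ms,
                                seed = as.integer(seed)))
  if (!is.null(acs))
    h5_write_complex(path, "acs", acs$data,
                     attrs = list(mode = acs$mode,
                                  ky_origin = acs$ky_origin))
  invisible(path)
}

#' Read the package's internal simulation container
#'
#' @param path HDF5 file written by [write_sim_h5()].
#' @return list with `echoes` (list of [mc_kspace]), `acs` ([acs_block] or
#'   `NULL`), `echo_times_ms` and `seed`.
#' @export
read_sim_h5 <- function(path) {
  arr <- h5_read_complex(path, "kspace")
  at <- attr(arr, "h5attrs")
  echoes <- lapply(seq_len(dim(arr)[1]), function(e)
    mc_kspace(array(arr[e, , , ], dim(arr)[2:4])))
  acs <- NULL
  info <- tryCatch({
    metafile <- tempfile(fileext = ".json")
    on.exit(unlink(metafile), add = TRUE)
    run_bridge(c("info", shQuote(path), shQuote(metafile)))
    jsonlite::fromJSON(metafile)
  }, error = function(e) NULL)
  if (!is.null(info) && "acs" %in% names(info)) {
    a <- h5_read_complex(path, "acs")
    aat <- attr(a, "h5attrs")
    acs <- acs_block(array(a, dim(a)), mode = aat$mode,
                     ky_origin = as.integer(aat$ky_origin))
  }
  list(echoes = echoes, acs = acs,
       echo_times_ms = as.numeric(at$echo_times_ms),
       seed = as.integer(at$seed))
}
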