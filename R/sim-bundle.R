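#' Write a synthetic two-channel fixture bundle to disk
#'
#' Renders both channels for a configuration and writes: `ca.tif` and
#' `trachea.tif` (multi-page 16-bit grayscale TIFF), the ground-truth
#' tables `ground_truth_events.csv`, `ground_truth_filopodia.csv` (one row
#' per filopodium) and `ground_truth_filopodia_frames.csv` (per-frame tip
#' positions), a `config.yaml` echo, and `manifest.json` listing each
#' file's MD5 hash. Two runs with the same configuration (and seed)
#' produce byte-identical CSVs.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a tibble (`file`, `md5`, `bytes`), invisibly
#'   written to `manifest.json`.
#' @export
write_fixture_bundle <- function(cfg, out_dir) {
  cfg <- validate_sim_config(cfg)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'.", out_dir))
  }
  probe <- file.path(out_dir, ".write_probe")
  if (inherits(try(writeLines("x", probe), silent = TRUE), "try-error")) {
    abort(sprintf("output directory '%s' is not writable.", out_dir))
  }
  unlink(probe)

  ca <- generate_ca_movie(cfg)
  tr <- generate_trachea_movie(cfg, ca$events)

  paths <- c(ca = file.path(out_dir, "ca.tif"),
             trachea = file.path(out_dir, "trachea.tif"),
             events = file.path(out_dir, "ground_truth_events.csv"),
             filopodia = file.path(out_dir, "ground_truth_filopodia.csv"),
             frames = file.path(out_dir, "ground_truth_filopodia_frames.csv"),
             config = file.path(out_dir, "config.yaml"))
  write_movie_tiff(ca$movie, paths["ca"])
  write_movie_tiff(tr$movie, paths["trachea"])
  readr::write_csv(ca$events, paths["events"])
  readr::write_csv(tr$filopodia, paths["filopodia"])
  readr::write_csv(tr$frames, paths["frames"])
  write_sim_config(cfg, paths["config"])

  manifest <- tibble(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    bytes = unname(file.size(unname(paths))),
    n_rows = c(NA, NA, nrow(ca$events), nrow(tr$filopodia), nrow(tr$frames), NA))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
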