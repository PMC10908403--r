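# On-disk population layout (format "synthetic_csv"):
#   <dir>/manifest.json             geometry, ground truth, wave file index
#   <dir>/<id>_<site>_<modality>.csv   '# key: value' header lines, then t,value
# Numbers are written with 17 significant digits so a write -> read round
# trip reproduces doubles bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

write_wave_csv <- function(wave, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# site: %s", wave$site),
               sprintf("# modality: %s", wave$modality),
               sprintf("# fs: %s", fmt_num(wave$fs)),
               "t,value"), con)
  t <- pw_time(wave)
  writeLines(paste(fmt_num(t), fmt_num(wave$samples), sep = ","), con)
}

read_wave_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  pulse_wave(df$value, fs = as.numeric(meta$fs), site = meta$site,
             modality = meta$modality)
}

seg_to_list <- function(s)
  list(length = s$length, r_in = s$r_in, r_out = s$r_out,
       k1 = s$k1, k2 = s$k2, k3 = s$k3, h_over_r = s$h_over_r)

seg_from_list <- function(l)
  arterial_segment(l$length, l$r_in, l$r_out, l$k1, l$k2, l$k3, l$h_over_r)

#' Write a population to a directory
#'
#' Emits one CSV file per waveform plus a JSON manifest holding ids, ages,
#' heights, geometry (aortic segments and path lengths) and the ground
#' truth.  The layout round-trips bit-exactly through [load_population()].
#'
#' @param population a `synthetic_population` (or list with `subjects`,
#'   `truths`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subs <- population$subjects
  trs <- population$truths
  entries <- lapply(seq_along(subs), function(i) {
    s <- subs[[i]]; tr <- trs[[i]]
    wave_files <- list()
    for (key in names(s$waves)) {
      w <- s$waves[[key]]
      fn <- sprintf("%s_%s_%s.csv", s$id, w$site, w$modality)
      write_wave_csv(w, file.path(dir, fn))
      wave_files[[key]] <- fn
    }
    truth <- NULL
    if (!is.null(tr)) {
      truth <- list(E_Ao = tr$E_Ao, aoPWVt = tr$aoPWVt,
                    transit_delays = as.list(tr$transit_delays),
                    DC_true = tr$DC_true, onset_time = tr$onset_time,
                    reflection_delay = tr$reflection_delay,
                    reflection_gain_eff = tr$reflection_gain_eff,
                    dbp = tr$dbp,
                    site_delays = as.list(tr$site_delays))
    }
    list(id = s$id, age = s$age, height = s$height, rho = s$rho,
         aortic_path = lapply(s$aortic_path, seg_to_list),
         path_lengths = as.list(s$path_lengths),
         waves = wave_files, truth = truth)
  })
  jsonlite::write_json(list(format = "pwva_population", version = 1,
                            subjects = entries),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a population from disk
#'
#' Reads either the package's CSV + JSON-manifest layout
#' (`format = "synthetic_csv"`) or a MATLAB-container accession
#' (`format = "zenodo_matlab"`, converted through a documented field
#' mapping; see `system.file("extdata", "zenodo_matlab_mapping.json",
#' package = "pwva")`).  Subjects with missing waveform files load with a
#' flag rather than being dropped; the indices that need the absent signal
#' are later reported missing by [compute_panel()].
#'
#' @param path population directory (or `.mat` container for the accession
#'   format).
#' @param format `"synthetic_csv"` or `"zenodo_matlab"`.
#' @return object of class `population_handle` with fields `source`,
#'   `format`, `ids` and lazy subject access via [get_subject()];
#'   [as_population()] materialises every subject.
#' @export
load_population <- function(path, format = c("synthetic_csv",
                                             "zenodo_matlab")) {
  format <- match.arg(format)
  if (format == "zenodo_matlab") path <- zenodo_to_csv(path)
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  ids <- vapply(manifest$subjects, function(s) s$id, "")
  structure(list(source = path, format = format, ids = ids,
                 manifest = manifest),
            class = "population_handle")
}

#' @export
print.population_handle <- function(x, ...) {
  cat(sprintf("<population_handle> %s (%s): %d subjects\n",
              x$source, x$format, length(x$ids)))
  invisible(x)
}

#' @rdname load_population
#' @param handle a `population_handle`.
#' @param id a subject id from `handle$ids`.
#' @export
get_subject <- function(handle, id) {
  stopifnot(inherits(handle, "population_handle"))
  k <- match(id, handle$ids)
  if (is.na(k)) stop("unknown subject id: ", id)
  e <- handle$manifest$subjects[[k]]
  waves <- list()
  flags <- character()
  for (key in names(e$waves)) {
    fn <- file.path(handle$source, e$waves[[key]])
    if (!file.exists(fn)) {
      flags <- c(flags, sprintf("missing wave file: %s", e$waves[[key]]))
      next
    }
    waves[[key]] <- read_wave_csv(fn)
  }
  subj <- virtual_subject(
    id = e$id, age = e$age, height = e$height, rho = e$rho,
    aortic_path = lapply(e$aortic_path, seg_from_list),
    path_lengths = unlist(e$path_lengths),
    waves = waves)
  truth <- NULL
  if (!is.null(e$truth)) {
    truth <- e$truth
    truth$transit_delays <- unlist(truth$transit_delays)
    truth$site_delays <- unlist(truth$site_delays)
    class(truth) <- "ground_truth"
  }
  if (length(flags)) attr(subj, "flags") <- flags
  list(subject = subj, truth = truth)
}

#' @rdname load_population
#' @export
as_population <- function(handle) {
  stopifnot(inherits(handle, "population_handle"))
  got <- lapply(handle$ids, function(id) get_subject(handle, id))
  structure(list(subjects = lapply(got, `[[`, "subject"),
                 truths = lapply(got, `[[`, "truth"),
                 spec = NULL),
            class = "synthetic_population")
}

# Convert a MATLAB-container accession into the CSV layout using the field
# mapping shipped with the package.  The container schema is not part of
# this package's contract: all layout knowledge lives in the mapping file,
# and the conversion shells out to a Python helper (scipy.io) since no
# MATLAB reader is available in R here.
zenodo_to_csv <- function(path,
                          mapping = system.file("extdata",
                                                "zenodo_matlab_mapping.json",
                                                package = "pwva"),
                          out_dir = tempfile("pwva_zenodo_")) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  helper <- system.file("python", "zenodo_convert.py", package = "pwva")
  status <- system2("python", c(helper, shQuote(path), shQuote(mapping),
                                shQuote(out_dir)))
  if (!identical(status, 0L))
    stop("MATLAB container conversion failed (status ", status, ")")
  out_dir
}

#' Export index panels as a CSV table
#'
#' One row per subject, one column per index plus `age` and (optionally)
#' the reference `E_Ao`.  Missing index values become empty cells, never 0.
#'
#' @param panels list of [index_panel] objects, or the data frame returned
#'   by [population_panels()].
#' @param truths optional numeric vector of `E_Ao` values (same length).
#' @param path output CSV path.
#' @param ages optional numeric vector of ages.
#' @return `path`, invisibly.
#' @export
export_panel_table <- function(panels, truths = NULL, path, ages = NULL) {
  if (is.data.frame(panels)) {
    df <- panels
  } else {
    if (!length(panels)) stop("panels must be non-empty")
    df <- do.call(rbind, lapply(panels, as.data.frame))
    if (!is.null(ages)) df <- cbind(age = ages, df)
  }
  if (!is.null(truths)) {
    if (length(truths) != nrow(df))
      stop("length mismatch between panels and truths")
    if (!"E_Ao" %in% names(df)) df <- cbind(df, E_Ao = truths)
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, fmt_num(x)))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname export_panel_table
#' @export
read_panel_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
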