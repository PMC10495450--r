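## File formats: segment tables (CSV/JSON, millimetre columns), waveforms
## (two-column CSV), recipe files (JSON) and Windkessel BC exports (JSON).
## All exports serialise numbers at full precision and add a 3-significant-
## figure display field mirroring published tables; exports re-read equal.

SEGMENT_HEADER <- c("label", "name", "diameter_mm", "length_mm", "count",
                    "group")

## 15 significant digits: enough to reproduce table values exactly while
## keeping the mm <-> m unit conversion idempotent across round trips.
num_full <- function(x) sprintf("%.15g", x)

validate_segment_rows <- function(df, path) {
  if (!identical(names(df), SEGMENT_HEADER))
    stop(sprintf("%s: header must be exactly `%s`", path,
                 paste(SEGMENT_HEADER, collapse = ",")), call. = FALSE)
  ## line = data row index + 1 (header line)
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    r <- df[i, ]
    if (is.na(r$label) || !nzchar(r$label))
      stop(sprintf("%s line %d: empty label", path, line), call. = FALSE)
    for (f in c("diameter_mm", "length_mm")) {
      v <- suppressWarnings(as.numeric(r[[f]]))
      if (is.na(v) || v <= 0)
        stop(sprintf("%s line %d: `%s` must be a positive number (got %s)",
                     path, line, f, r[[f]]), call. = FALSE)
    }
    if (!is.na(r$count) && suppressWarnings(as.numeric(r$count)) <= 0)
      stop(sprintf("%s line %d: `count` must be > 0", path, line),
           call. = FALSE)
    if (!(r$group %in% SEGMENT_GROUPS))
      stop(sprintf("%s line %d: unknown group `%s` (valid: %s)", path, line,
                   r$group, paste(SEGMENT_GROUPS, collapse = ", ")),
           call. = FALSE)
  }
  dup <- df$label[duplicated(df$label)]
  if (length(dup))
    stop(sprintf("%s: duplicate label `%s`", path, dup[1]), call. = FALSE)
  invisible(df)
}

#' Read a vessel segment table
#'
#' Reads a CSV (header `label,name,diameter_mm,length_mm,count,group`) or a
#' JSON array with identical field names.  Geometry is converted from
#' millimetres to metres; a missing count means one copy; row order is
#' preserved.  Malformed rows are rejected with the offending line number.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return A data frame of class `segment_table` with SI columns `label`,
#'   `name`, `diameter`, `length`, `multiplicity`, `group`.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(lst, stringsAsFactors = FALSE)
    if (!("count" %in% names(df))) df$count <- NA_real_
    df <- df[, SEGMENT_HEADER[SEGMENT_HEADER %in% names(df)], drop = FALSE]
  } else {
    hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    if (!identical(hdr, SEGMENT_HEADER))
      stop(sprintf("%s: header must be exactly `%s`", path,
                   paste(SEGMENT_HEADER, collapse = ",")), call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(label = "character",
                                         name = "character",
                                         group = "character"))
  }
  validate_segment_rows(df, path)
  out <- data.frame(label = df$label, name = df$name,
                    diameter = as.numeric(df$diameter_mm) * 1e-3,
                    length = as.numeric(df$length_mm) * 1e-3,
                    multiplicity = ifelse(is.na(df$count), 1,
                                          as.numeric(df$count)),
                    group = df$group, stringsAsFactors = FALSE)
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Write a vessel segment table
#'
#' Inverse of [read_segment_table()]: writes the millimetre-unit CSV or
#' JSON schema at full precision, so that export/import/export round-trips
#' byte-identically.
#'
#' @param segments A `segment_table` data frame (SI units).
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  stopifnot(is.data.frame(segments))
  out <- data.frame(label = segments$label, name = segments$name,
                    diameter_mm = num_full(segments$diameter * 1e3),
                    length_mm = num_full(segments$length * 1e3),
                    count = num_full(segments$multiplicity),
                    group = segments$group, stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a flow waveform from CSV
#'
#' Two-column CSV `time_s,flow_m3s` covering one period.  The period is the
#' last time value if it exceeds the penultimate sample's spacing hint, or
#' can be given explicitly.
#'
#' @param path CSV path.
#' @param period Cycle period in s; default: inferred as the last time
#'   sample plus one grid spacing when the grid looks uniform and open, or
#'   the last sample when it closes the cycle.
#' @return A [waveform()].
#' @export
read_waveform <- function(path, period = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "flow_m3s") %in% names(df)))
    stop(path, ": waveform CSV needs columns time_s,flow_m3s", call. = FALSE)
  t <- df$time_s
  q <- df$flow_m3s
  if (is.null(period)) {
    n <- length(t)
    last_step <- t[n] - t[n - 1]
    ## closed grid (flow repeats) vs open uniform grid
    period <- if (abs(q[n] - q[1]) <= 1e-9 * max(abs(q), 1e-300)) t[n]
              else t[n] + last_step
  }
  waveform(period, t, q)
}

#' Write a flow waveform to CSV
#'
#' @param wf A [waveform()].
#' @param path Output CSV path (`time_s,flow_m3s`).
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "waveform"))
  df <- data.frame(time_s = num_full(wf$time), flow_m3s = num_full(wf$flow))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

recipes_to_json_list <- function(recipes) {
  lapply(unname(recipes), function(r) {
    ch <- lapply(seq_along(r$refs), function(j) {
      e <- list(ref = r$refs[j], factor = r$factors[j])
      if (!is.null(r$stated_factors) && !is.na(r$stated_factors[j]) &&
          r$stated_factors[j] != r$factors[j])
        e$stated_factor <- r$stated_factors[j]
      e
    })
    list(name = r$name, mode = r$mode, children = ch)
  })
}

#' Write reduction recipes to JSON
#'
#' Schema: an array of `{name, mode, children: [{ref, factor}]}` entries,
#' or an object with `resistance` and `compliance` arrays when given a
#' paired list of chains.
#'
#' @param recipes A [recipe_table()], or a list with components
#'   `resistance` and `compliance`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_recipes <- function(recipes, path) {
  body <- if (inherits(recipes, "recipe_table")) {
    recipes_to_json_list(recipes)
  } else {
    lapply(recipes, recipes_to_json_list)
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read reduction recipes from JSON
#'
#' @param path JSON path written by [write_recipes()] (or hand-authored in
#'   the same schema).
#' @return A [recipe_table()], or a list of them when the file holds
#'   multiple named chains.
#' @export
read_recipes <- function(path) {
  js <- jsonlite::read_json(path)
  if (!is.null(js$name) || (length(js) && !is.null(js[[1]]$name)))
    return(parse_recipe_json(js))
  lapply(js, parse_recipe_json)
}

#' Export Windkessel boundary conditions to JSON
#'
#' Solver-agnostic schema, one record per outlet:
#' `{outlet, Rp, C, Rd, distal_pressure, units: "SI", provenance,
#' display: {...}}` where the display block repeats the parameters at
#' 3 significant figures for eyeballing against published tables.
#'
#' @param bcs Named list of [windkessel_bc()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_bc_json <- function(bcs, path) {
  recs <- lapply(names(bcs), function(nm) {
    b <- bcs[[nm]]
    list(outlet = nm,
         Rp = b$proximal_resistance,
         C = b$compliance,
         Rd = b$distal_resistance,
         distal_pressure = b$distal_pressure,
         units = "SI",
         provenance = b$provenance,
         display = list(Rp = signif(b$proximal_resistance, 3),
                        C = signif(b$compliance, 3),
                        Rd = signif(b$distal_resistance, 3)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read Windkessel boundary conditions from JSON
#'
#' @param path JSON path written by [write_bc_json()].
#' @return Named list of [windkessel_bc()] objects.
#' @export
read_bc_json <- function(path) {
  recs <- jsonlite::read_json(path)
  bcs <- lapply(recs, function(r)
    windkessel_bc(r$Rp, r$C, r$Rd, r$distal_pressure,
                  provenance = r$provenance))
  stats::setNames(bcs, vapply(recs, `[[`, character(1), "outlet"))
}

#' Export a simulation result as tidy CSV plus a JSON summary
#'
#' Writes `<prefix>.csv` with columns `time_s,pressure_pa` and one
#' `flow_<outlet>_m3s` column per outlet, and `<prefix>_summary.json` with
#' the cycle count, convergence flag and mean split fractions.
#'
#' @param sim A `wk_sim` result from [multi_outlet_split()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_sim_result <- function(sim, prefix) {
  stopifnot(inherits(sim, "wk_sim"))
  df <- data.frame(time_s = sim$time, pressure_pa = sim$pressure)
  for (nm in colnames(sim$flows))
    df[[paste0("flow_", nm, "_m3s")]] <- sim$flows[, nm]
  csv <- paste0(prefix, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  js <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(cycles = sim$cycles_run,
                            converged = sim$converged,
                            converged_cycle = sim$converged_cycle,
                            mean_splits = as.list(sim$mean_splits)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Export the bundled atlas
#'
#' Writes the atlas segment table (standard schema, geometric rows), the
#' active dialect's recipes and the topology into a directory.
#'
#' @param atlas A [load_atlas()] object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_atlas <- function(atlas = load_atlas(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- atlas$rows[!is.na(atlas$rows$diameter), ]
  seg <- data.frame(label = rows$label, name = rows$name,
                    diameter = rows$diameter, length = rows$length,
                    multiplicity = rows$multiplicity, group = rows$group,
                    stringsAsFactors = FALSE)
  class(seg) <- c("segment_table", "data.frame")
  write_segment_table(seg, file.path(dir, "segments.csv"))
  write_recipes(atlas$recipes, file.path(dir, "recipes.json"))
  utils::write.csv(atlas$topology, file.path(dir, "topology.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
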