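#' @title CSV input/output
#'
#' @description All artifacts are plain UTF-8 CSV ("." decimal, ","
#' separator, mandatory header).  Files open with "#"-prefixed comment
#' lines recording the package version, a config digest and any seeds, so
#' every output is traceable; readers skip those lines.
#' @name io
NULL

meta_header <- function(meta = list()) {
  # no timestamp: identical invocations must produce byte-identical files
  meta <- c(list(tool = paste0("nutriscape ",
                               as.character(utils::packageVersion("nutriscape")))),
            meta)
  meta$config_hash <- config_hash(meta)
  paste0("# ", names(meta), ": ",
         vapply(meta, function(x) paste(format(x), collapse = ","), ""))
}

# Order-independent FNV-1a style digest of the serialized key=value pairs;
# enough to detect config drift between runs, not cryptographic.
config_hash <- function(config) {
  s <- paste(sort(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), ""), sep = "=")), collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_csv_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_skip_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a design CSV
#'
#' Columns: strategy, point_id, protein_gL, carbohydrate_gL, rail_ratio
#' (empty when not a GF design), concentration (idem).
#'
#' @param design A `nutri_design`.
#' @param path File path.
#' @return `write_design_csv` returns the path invisibly;
#'   `read_design_csv` returns a `nutri_design`.
#' @export
write_design_csv <- function(design, path) {
  df <- data.frame(strategy = attr(design, "strategy"),
                   point_id = seq_len(nrow(design)),
                   protein_gL = design$p, carbohydrate_gL = design$c,
                   rail_ratio = design$rail_ratio,
                   concentration = design$concentration)
  sp <- attr(design, "space")
  write_csv_with_meta(df, path, meta = list(
    strategy = attr(design, "strategy"),
    resolution = attr(design, "resolution"),
    space = c(sp$p_min, sp$p_max, sp$c_min, sp$c_max),
    cell_apothem = attr(design, "cell_apothem"),
    seed = attr(design, "seed")))
}

#' @rdname write_design_csv
#' @param space The design's [nutrient_space()] (CSV metadata is
#'   informative only; the space must be re-supplied).
#' @export
read_design_csv <- function(path, space = nutrient_space()) {
  df <- read_csv_skip_meta(path)
  need <- c("strategy", "protein_gL", "carbohydrate_gL")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design CSV missing column(s): ", paste(miss, collapse = ", "))
  pts <- data.frame(p = df$protein_gL, c = df$carbohydrate_gL,
                    rail_ratio = if ("rail_ratio" %in% names(df))
                      df$rail_ratio else NA_real_,
                    concentration = if ("concentration" %in% names(df))
                      df$concentration else NA_real_)
  new_design(pts, df$strategy[1L], nrow(pts), space)
}

#' Write / read a landscape CSV
#'
#' Columns: trait, protein_gL, carbohydrate_gL, value.  Values round-trip
#' losslessly (written at full double precision).
#'
#' @param landscape A `landscape`.
#' @param path File path.
#' @export
write_landscape_csv <- function(landscape, path) {
  df <- data.frame(trait = attr(landscape, "trait"),
                   protein_gL = landscape$p, carbohydrate_gL = landscape$c,
                   value = format(landscape$value, digits = 17,
                                  scientific = TRUE, trim = TRUE))
  sp <- attr(landscape, "space")
  write_csv_with_meta(df, path, meta = c(list(
    trait = attr(landscape, "trait"),
    spacing = attr(landscape, "spacing"),
    space = c(sp$p_min, sp$p_max, sp$c_min, sp$c_max)),
    attr(landscape, "meta")))
}

#' @rdname write_landscape_csv
#' @param space,spacing Grid geometry to re-attach (the CSV records them in
#'   its comment header for humans; pass matching values here).
#' @export
read_landscape_csv <- function(path, space = nutrient_space(), spacing = 4) {
  df <- read_csv_skip_meta(path)
  need <- c("trait", "protein_gL", "carbohydrate_gL", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landscape CSV missing column(s): ", paste(miss, collapse = ", "))
  new_landscape(data.frame(p = df$protein_gL, c = df$carbohydrate_gL),
                as.numeric(df$value), df$trait[1L], spacing, space)
}

#' Read a diet-trait table
#'
#' Expects protein and carbohydrate concentration columns plus one column
#' per trait.  Rows with missing values in the requested trait columns are
#' dropped with a warning giving the count.  Column names can be remapped
#' for externally produced tables (e.g. a published dataset) without
#' editing the file.
#'
#' @param path CSV path ("#" comment lines allowed).
#' @param mapping Named character vector mapping internal names to file
#'   column names, e.g. `c(p = "protein_gL", c = "carbohydrate_gL")`.
#' @param traits Trait columns to keep; default: all remaining columns.
#' @return Data.frame with columns `p`, `c` and the trait columns.
#' @export
read_diet_table <- function(path,
                            mapping = c(p = "protein_gL",
                                        c = "carbohydrate_gL"),
                            traits = NULL) {
  df <- read_csv_skip_meta(path)
  miss <- setdiff(unname(mapping), names(df))
  if (length(miss))
    stop("diet table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(p = df[[mapping[["p"]]]], c = df[[mapping[["c"]]]])
  if (is.null(traits))
    traits <- setdiff(names(df),
                      c(unname(mapping), "point_id", "strategy",
                        "rail_ratio", "concentration"))
  if (!length(traits)) stop("no trait columns found in diet table")
  out <- cbind(out, df[, traits, drop = FALSE])
  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a diet-trait table
#'
#' @param table Data.frame with columns `p`, `c` and trait columns.
#' @param path File path.
#' @param meta Named list for the comment header.
#' @export
write_diet_table <- function(table, path, meta = list()) {
  df <- table
  names(df)[names(df) == "p"] <- "protein_gL"
  names(df)[names(df) == "c"] <- "carbohydrate_gL"
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 17, scientific = TRUE, trim = TRUE))
  write_csv_with_meta(df, path, meta = meta)
}
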