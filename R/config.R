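# Spin-system config files: a minimal TOML dialect with top-level scalar
# keys and [[spin]] tables. Only the subset needed here is supported:
# numeric scalars, numeric arrays, and double-quoted strings.

.parse_toml_value <- function(txt) {
  txt <- trimws(txt)
  if (startsWith(txt, "[")) {
    inner <- sub("^\\[", "", sub("\\]$", "", txt))
    parts <- strsplit(inner, ",")[[1]]
    return(vapply(parts, function(p) as.numeric(trimws(p)), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (startsWith(txt, "\"")) {
    return(gsub("^\"|\"$", "", txt))
  }
  as.numeric(txt)
}

#' Read a spin system from a config file
#'
#' The file holds top-level keys (`larmor_hz`, optional `gamma`) and one
#' `[[spin]]` block per spin with `position` (3-vector, Angstrom) and
#' `shift_ppm`.
#'
#' @param path Path to the config file.
#' @return A [spin_system()].
#' @export
#' @examples
#' path <- system.file("extdata", "three_spin.toml", package = "masmoments")
#' read_spin_system(path)
read_spin_system <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  top <- list()
  spins <- list()
  current <- NULL   # NULL = top level, otherwise index of open spin block
  for (ln in lines) {
    if (ln == "[[spin]]") {
      spins[[length(spins) + 1]] <- list()
      current <- length(spins)
      next
    }
    if (grepl("^\\[", ln)) abort(sprintf("Unsupported table in config: %s", ln))
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("Cannot parse config line: %s", ln))
    key <- trimws(kv[1])
    val <- .parse_toml_value(kv[2])
    if (is.null(current)) top[[key]] <- val else spins[[current]][[key]] <- val
  }
  if (length(spins) < 2) abort("Config must define at least two [[spin]] blocks.")
  pos <- t(vapply(spins, function(s) {
    if (is.null(s$position) || length(s$position) != 3) {
      abort("Each [[spin]] needs a 3-vector `position`.")
    }
    s$position
  }, numeric(3)))
  shift <- vapply(spins, function(s) s$shift_ppm %||% 0, numeric(1))
  spin_system(
    data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], shift_ppm = shift),
    larmor_hz = top$larmor_hz %||% 1e9,
    gamma = top$gamma %||% gamma_proton()
  )
}

#' Write a spin system to a config file
#'
#' @param system A [spin_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(system, path) {
  stopifnot(inherits(system, "spin_system"))
  num <- function(x) format(x, digits = 15)
  out <- c(
    sprintf("larmor_hz = %s", num(system$larmor_hz)),
    sprintf("gamma = %s", num(system$gamma))
  )
  for (k in seq_len(nrow(system$spins))) {
    out <- c(
      out, "", "[[spin]]",
      sprintf("position = [%s, %s, %s]",
              num(system$spins$x[k]), num(system$spins$y[k]),
              num(system$spins$z[k])),
      sprintf("shift_ppm = %s", num(system$spins$shift_ppm[k]))
    )
  }
  writeLines(out, path)
  invisible(path)
}
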