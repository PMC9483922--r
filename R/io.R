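# Readers and writers: PQR frames (whitespace-delimited dialect, MODEL /
# ENDMDL frame delimiters, CRYST1 box records), OpenDX scalar fields for
# potential grids, and CSV run sets.  All writes go through a
# write-then-rename so a crash never leaves a truncated file.

atomic_write <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to write ", path, call. = FALSE)
  }
  invisible(path)
}

.species_to_res <- c(solvent = "SOL", protein = "PRO", membrane = "MEM")
.res_to_species <- c(
  SOL = "solvent", WAT = "solvent", HOH = "solvent", TIP3 = "solvent",
  ION = "solvent",
  PRO = "protein",
  MEM = "membrane", POPC = "membrane", POPG = "membrane", LIP = "membrane"
)

#' Write charge systems to a PQR file
#'
#' Whitespace-delimited PQR: `ATOM serial name resName resSeq x y z charge
#' radius`.  Species labels map to residue names (`SOL`, `PRO`, `MEM`).
#' Multiple frames are written as `MODEL`/`ENDMDL` blocks, each preceded by
#' its own `CRYST1` box record so per-frame box dimensions survive the round
#' trip.
#'
#' @param frames A [charge_system()] or list of them.
#' @param path Output path.
#' @param radius Per-atom radius column (A), default 1.
#' @return The path, invisibly.
#' @export
write_pqr <- function(frames, path, radius = 1) {
  if (inherits(frames, "charge_system")) frames <- list(frames)
  lines <- character(0)
  multi <- length(frames) > 1
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    if (multi) lines <- c(lines, sprintf("MODEL %8d", fi))
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
      fr$box[1], fr$box[2], fr$box[3]))
    res <- if (is.null(fr$species)) rep("UNK", n_particles(fr)) else
      unname(.species_to_res[fr$species])
    lines <- c(lines, sprintf(
      "ATOM %6d %-4s %-4s %5d %11.4f %11.4f %11.4f %8.4f %8.4f",
      seq_len(n_particles(fr)), "PT", res, seq_len(n_particles(fr)),
      fr$positions[, 1], fr$positions[, 2], fr$positions[, 3],
      fr$charges, radius))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  atomic_write(lines, path)
}

#' Read charge-system frames from a PQR file
#'
#' Parses `ATOM`/`HETATM` records of the whitespace-delimited PQR dialect;
#' the last five numeric fields of each record are taken as x, y, z, charge
#' and radius, so both chain-bearing and chain-free dialects parse.
#' `MODEL`/`ENDMDL` delimit frames; each frame's box comes from the
#' preceding `CRYST1` record (an error is raised if none is present).
#' Species labels are recovered from residue names where recognized
#' (`SOL`/`WAT`/`HOH`/`TIP3`/`ION` solvent, `PRO` protein,
#' `MEM`/`POPC`/`POPG`/`LIP` membrane).
#'
#' @param path Input path.
#' @return A list of [charge_system()] frames, in file order.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  cur <- list()
  flush_frame <- function(cur, box) {
    if (length(cur) == 0) return(NULL)
    if (is.null(box)) {
      stop("PQR frame has no CRYST1 box record: ", path, call. = FALSE)
    }
    m <- do.call(rbind, lapply(cur, `[[`, "num"))
    res <- vapply(cur, `[[`, "", "res")
    species <- unname(.res_to_species[res])
    if (any(is.na(species))) species <- NULL
    charge_system(m[, 1:3, drop = FALSE], m[, 4], box, species = species)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "CRYST1")) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      box <- as.numeric(f[2:4])
    } else if (startsWith(line, "MODEL")) {
      cur <- list()
    } else if (startsWith(line, "ENDMDL")) {
      frames[[length(frames) + 1]] <- flush_frame(cur, box)
      cur <- list()
    } else if (startsWith(line, "ATOM") || startsWith(line, "HETATM")) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      suppressWarnings(nums <- as.numeric(f))
      if (length(which(!is.na(nums))) < 5) {
        stop("PQR line ", ln, " lacks x y z charge radius fields: ",
             trimws(line), call. = FALSE)
      }
      tail5 <- sort(utils::tail(which(!is.na(nums)), 5))
      cur[[length(cur) + 1]] <- list(num = nums[tail5], res = f[4])
    }
  }
  if (length(cur) > 0) frames[[length(frames) + 1]] <- flush_frame(cur, box)
  if (length(frames) == 0) stop("no atoms found in ", path, call. = FALSE)
  frames
}

#' Write a potential grid as an OpenDX scalar field
#'
#' Standard OpenDX regular-grid scalar field; origin and deltas in
#' angstrom, data values in mV written three per line with the last (z)
#' index varying fastest, per the OpenDX convention.
#'
#' @param grid A [potential_grid()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  d <- grid$dims
  # z fastest: traverse values with x slowest
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  n <- length(vals)
  rows <- split(vals, ceiling(seq_len(n) / 3))
  data_lines <- vapply(rows, function(v) {
    paste(sprintf("%.8e", v), collapse = " ")
  }, "")
  lines <- c(
    "# OpenDX scalar field: tinfoil Ewald potential (mV)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing[1]),
    sprintf("delta 0 %.6f 0", grid$spacing[2]),
    sprintf("delta 0 0 %.6f", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n),
    data_lines,
    'attribute "dep" string "positions"',
    'object "field" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  )
  atomic_write(lines, path)
}

#' Read an OpenDX scalar field into a potential grid
#'
#' @param path Input path.
#' @return A [potential_grid()].
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  og <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(og), "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  sp <- vapply(1:3, function(i) {
    as.numeric(strsplit(trimws(deltas[i]), "\\s+")[[1]][i + 1])
  }, 1.0)
  start <- grep("data follows", lines)[1] + 1
  stop_at <- grep('attribute "dep"', lines)[1] - 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:stop_at]), "\\s+")))
  stopifnot(length(vals) == prod(d))
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  potential_grid(arr, box = d * sp, origin = origin)
}

#' Write / read run sets as CSV
#'
#' Columns `run_id`, `pH`, `phi_mV`, `T_K`, `snapshot`, `n_protons` plus a
#' `# n_sites = <k>` comment header; `read_runset()` restores the `runset`
#' class and attribute, so `read_runset(write_runset(x))` is the identity.
#'
#' @param runs A run-set tibble.
#' @param path File path.
#' @return `write_runset()` the path invisibly; `read_runset()` a `runset`.
#' @name runset_io
#' @export
write_runset <- function(runs, path) {
  stopifnot(inherits(runs, "runset"))
  header <- sprintf("# n_sites = %d", attr(runs, "n_sites"))
  body <- utils::capture.output(
    utils::write.csv(as.data.frame(runs), row.names = FALSE))
  atomic_write(c(header, body), path)
}

#' @rdname runset_io
#' @export
read_runset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  ns <- as.integer(sub(".*n_sites\\s*=\\s*", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  new_runset(tibble::as_tibble(df), n_sites = ns)
}
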