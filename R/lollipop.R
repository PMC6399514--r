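#' Lollipop pattern table of a call matrix
#'
#' @param m call matrix (clones x sites; 1/0/NA).
#' @return character matrix of the same shape with values `"filled"`
#'   (methylated), `"open"` (unmethylated), `"absent"` (missing).
#' @export
lollipop_matrix <- function(m) {
  m <- as.matrix(m)
  out <- matrix("absent", nrow(m), ncol(m), dimnames = dimnames(m))
  out[!is.na(m) & m == 1L] <- "filled"
  out[!is.na(m) & m == 0L] <- "open"
  out
}

#' Text rendering of a lollipop matrix
#'
#' One line per clone: the clone id, whitespace, then one character per site
#' (`*` filled, `o` open, `.` absent). [parse_lollipop()] inverts it.
#'
#' @param m call matrix (clones x sites; 1/0/NA).
#' @return character vector of lines.
#' @export
format_lollipop <- function(m) {
  m <- as.matrix(m)
  sym <- ifelse(is.na(m), ".", ifelse(m == 1L, "*", "o"))
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("clone", seq_len(nrow(m)))
  body <- apply(sym, 1L, paste, collapse = "")
  sprintf("%-*s %s", max(nchar(ids)), ids, body)
}

#' Parse a text lollipop rendering back into a call matrix
#'
#' @param lines character vector as produced by [format_lollipop()].
#' @return integer call matrix (1/0/NA) with clone ids as row names.
#' @export
parse_lollipop <- function(lines) {
  parts <- regmatches(lines, regexec("^(\\S+)\\s+([*o.]+)$", lines))
  if (any(lengths(parts) != 3L)) stop("unparseable lollipop line")
  ids <- vapply(parts, `[`, "", 2L)
  pat <- vapply(parts, `[`, "", 3L)
  if (length(unique(nchar(pat))) != 1L) stop("ragged lollipop lines")
  ch <- do.call(rbind, strsplit(pat, ""))
  m <- matrix(NA_integer_, nrow(ch), ncol(ch),
              dimnames = list(ids, paste0("CpG", seq_len(ncol(ch)))))
  m[ch == "*"] <- 1L
  m[ch == "o"] <- 0L
  m
}

#' Write an SVG lollipop diagram
#'
#' Clones as rows, CpG sites as columns; filled circles methylated, open
#' circles unmethylated, missing positions omitted.
#'
#' @param m call matrix (clones x sites; 1/0/NA).
#' @param path output file.
#' @param cell circle spacing in pixels.
#' @return `path`, invisibly.
#' @export
write_lollipop_svg <- function(m, path, cell = 16) {
  m <- as.matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  left <- 90; top <- 30; r <- cell * 0.33
  wdt <- left + nc * cell + 20; hgt <- top + nr * cell + 20
  ids <- rownames(m); if (is.null(ids)) ids <- paste0("clone", seq_len(nr))
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   ceiling(wdt), ceiling(hgt)),
           sprintf('<text x="%g" y="%g" font-size="10">CpG1..CpG%d</text>',
                   left, top - 10, nc))
  for (i in seq_len(nr)) {
    y <- top + (i - 0.5) * cell
    out <- c(out, sprintf('<text x="5" y="%g" font-size="10">%s</text>',
                          y + 3, ids[i]))
    for (j in seq_len(nc)) {
      if (is.na(m[i, j])) next
      fill <- if (m[i, j] == 1L) "black" else "white"
      out <- c(out, sprintf(
        '<circle cx="%g" cy="%g" r="%g" fill="%s" stroke="black"/>',
        left + (j - 0.5) * cell, y, r, fill))
    }
  }
  writeLines(c(out, "</svg>"), path)
  invisible(path)
}

#' Lollipop plot of a BSP fit
#'
#' Draws the clone-by-site methylation pattern for one group (filled circles
#' methylated, open unmethylated; missing positions blank), the standard
#' presentation of clone-based bisulfite sequencing results.
#'
#' @param x a `bsp_fit`.
#' @param group group to draw; default the first.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bsp_fit <- function(x, group = NULL, ...) {
  if (is.null(group)) group <- x$groups[1L]
  m <- x$matrices[[group]]
  if (is.null(m) || nrow(m) == 0L) stop("no retained clones in group ", group)
  nr <- nrow(m); nc <- ncol(m)
  graphics::plot(NA, xlim = c(0.5, nc + 0.5), ylim = c(nr + 0.5, 0.5),
                 xlab = "CpG site", ylab = "clone", axes = FALSE,
                 main = paste0("Methylation pattern, group ", group), ...)
  graphics::axis(1, at = seq_len(nc))
  graphics::axis(2, at = seq_len(nr), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  for (i in seq_len(nr)) {
    j <- which(!is.na(m[i, ]))
    graphics::points(j, rep(i, length(j)), pch = 21,
                     bg = ifelse(m[i, j] == 1L, "black", "white"), cex = 1.2)
  }
  invisible(x)
}
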