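# PDBx/mmCIF reading and writing.
#
# The engine needs every category of the file, including ones it will never
# renumber, carried through value-faithfully; tables are therefore held as
# ordered lists of named string columns and nothing is ever reinterpreted
# numerically.

# Split one line into CIF tokens. Handles '...' and "..." quoting and
# comments; semicolon text fields are handled by the caller.
tokenizeCifLine <- function(line) {
    if (!grepl("['\"#]", line, fixed = FALSE)) {
        toks <- strsplit(trimws(line), "[ \t]+")[[1L]]
        return(toks[nzchar(toks)])
    }
    chars <- strsplit(line, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    toks <- character()
    i <- 1L
    while (i <= n) {
        c0 <- chars[i]
        if (c0 %in% c(" ", "\t")) { i <- i + 1L; next }
        if (c0 == "#") break
        if (c0 %in% c("'", '"')) {
            # quoted value: closing quote must be followed by blank or EOL
            j <- i + 1L
            while (j <= n) {
                if (chars[j] == c0 &&
                    (j == n || chars[j + 1L] %in% c(" ", "\t"))) break
                j <- j + 1L
            }
            if (j > n) stop("unterminated quoted string", call. = FALSE)
            toks <- c(toks, paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                                  collapse = ""))
            i <- j + 1L
        } else {
            j <- i
            while (j <= n && !chars[j] %in% c(" ", "\t")) j <- j + 1L
            toks <- c(toks, paste(chars[i:(j - 1L)], collapse = ""))
            i <- j
        }
    }
    toks
}

#' Read an mmCIF file
#'
#' Parses both loop and key-value categories into an ordered set of string
#' tables; all values (including "." and "?") are kept verbatim so that an
#' unmodified document writes back with every value intact.
#'
#' @param path path to a `.cif` or `.cif.gz` file, or a character vector of
#'   lines (when `isLines = TRUE`).
#' @param gzipped force gzip interpretation; by default inferred from the
#'   file name.
#' @param isLines treat `path` as already-read lines.
#' @return An [MmcifDocument-class].
#' @examples
#' fx <- makeFixture(fixtureSpec(chainLength = 4), seed = 1)
#' fx$mmcif
#' @export
readMmcif <- function(path, gzipped = NA, isLines = FALSE) {
    if (isLines) {
        lines <- path
        gz <- FALSE
    } else {
        gz <- if (is.na(gzipped)) grepl("\\.gz$", path) else gzipped
        con <- if (gz) gzfile(path, "rt") else file(path, "rt")
        on.exit(close(con))
        lines <- readLines(con, warn = FALSE)
    }

    # token stream with line numbers; semicolon text fields become one token
    toksL <- list()
    tlinL <- list()
    tfL <- list()
    i <- 1L
    n <- length(lines)
    while (i <= n) {
        line <- lines[i]
        if (startsWith(line, ";")) {
            body <- substring(line, 2L)
            j <- i + 1L
            block <- character()
            while (j <= n && !startsWith(lines[j], ";")) {
                block <- c(block, lines[j])
                j <- j + 1L
            }
            if (j > n)
                stop("unterminated text field starting at line ", i,
                     call. = FALSE)
            toksL[[length(toksL) + 1L]] <- paste(c(body, block),
                                                 collapse = "\n")
            tlinL[[length(tlinL) + 1L]] <- i
            tfL[[length(tfL) + 1L]] <- TRUE
            i <- j + 1L
        } else {
            tl <- tryCatch(tokenizeCifLine(line), error = function(e)
                stop(conditionMessage(e), " at line ", i, call. = FALSE))
            if (length(tl)) {
                toksL[[length(toksL) + 1L]] <- tl
                tlinL[[length(tlinL) + 1L]] <- rep(i, length(tl))
                tfL[[length(tfL) + 1L]] <- rep(FALSE, length(tl))
            }
            i <- i + 1L
        }
    }
    toks <- unlist(toksL, use.names = FALSE) %||% character()
    tlin <- unlist(tlinL, use.names = FALSE) %||% integer()
    textfield <- unlist(tfL, use.names = FALSE) %||% logical()

    istag <- startsWith(toks, "_") & !textfield

    tables <- list()
    entryId <- ""
    k <- 1L
    nt <- length(toks)
    openTable <- NULL   # current non-loop table being accumulated

    flush <- function() {
        if (!is.null(openTable)) tables[[length(tables) + 1L]] <<- openTable
        openTable <<- NULL
    }
    splitTag <- function(tag) {
        dot <- regexpr(".", tag, fixed = TRUE)
        if (dot < 0L) list(cat = tag, item = "") else
            list(cat = substr(tag, 1L, dot - 1L),
                 item = substring(tag, dot + 1L))
    }

    while (k <= nt) {
        tk <- toks[k]
        if (!textfield[k] && startsWith(tk, "data_")) {
            entryId <- substring(tk, 6L)
            k <- k + 1L
        } else if (!textfield[k] && tk == "loop_") {
            flush()
            k <- k + 1L
            hdr <- character()
            while (k <= nt && istag[k]) {
                hdr <- c(hdr, toks[k])
                k <- k + 1L
            }
            if (!length(hdr))
                stop("loop_ without item names at line ", tlin[k - 1L],
                     call. = FALSE)
            first <- k
            while (k <= nt && !istag[k] && !(!textfield[k] &&
                   (toks[k] == "loop_" || startsWith(toks[k], "data_"))))
                k <- k + 1L
            vals <- toks[seq(first, length.out = k - first)]
            if (length(vals) %% length(hdr) != 0L)
                stop(sprintf("loop %s has %d values, not a multiple of %d columns (near line %d)",
                             splitTag(hdr[1L])$cat, length(vals), length(hdr),
                             tlin[first]), call. = FALSE)
            parts <- lapply(hdr, splitTag)
            cat <- parts[[1L]]$cat
            items <- vapply(parts, `[[`, "", "item")
            nrow <- length(vals) %/% length(hdr)
            data <- lapply(seq_along(hdr), function(ci)
                vals[seq(ci, length(vals), by = length(hdr))])
            names(data) <- items
            tables[[length(tables) + 1L]] <-
                list(category = cat, items = items, data = data, loop = TRUE)
        } else if (istag[k]) {
            if (k + 1L > nt)
                stop("item ", toks[k], " has no value (line ", tlin[k], ")",
                     call. = FALSE)
            p <- splitTag(toks[k])
            val <- toks[k + 1L]
            if (istag[k + 1L])
                stop("item ", toks[k], " has no value (line ", tlin[k], ")",
                     call. = FALSE)
            if (!is.null(openTable) && openTable$category == p$cat) {
                openTable$items <- c(openTable$items, p$item)
                openTable$data[[p$item]] <- val
            } else {
                flush()
                openTable <- list(category = p$cat, items = p$item,
                                  data = stats::setNames(list(val), p$item),
                                  loop = FALSE)
            }
            k <- k + 2L
        } else {
            stop("unexpected value ", sQuote(substr(tk, 1L, 30L)),
                 " at line ", tlin[k], call. = FALSE)
        }
    }
    flush()
    new("MmcifDocument", entryId = entryId, tables = tables, gzipped = gz)
}

needsQuoting <- function(v) {
    v == "" | grepl("[ \t]", v) |
        grepl("^['\"_#$\\[\\];]", v) |
        tolower(v) %in% c("loop_", "stop_", "global_") |
        startsWith(tolower(v), "data_") | startsWith(tolower(v), "save_")
}

formatCifValue <- function(v) {
    out <- v
    q <- needsQuoting(v) | grepl("\n", v, fixed = TRUE)
    multi <- grepl("\n", v, fixed = TRUE) |
        (grepl("'", v, fixed = TRUE) & grepl('"', v, fixed = TRUE))
    useq <- q & !multi
    single <- useq & !grepl("'", v, fixed = TRUE)
    dbl <- useq & !single
    out[single] <- paste0("'", v[single], "'")
    out[dbl] <- paste0('"', v[dbl], '"')
    out[multi] <- paste0("\n;", v[multi], "\n;\n")
    out
}

#' Write an mmCIF document
#'
#' @param doc an [MmcifDocument-class].
#' @param path output path; written gzip-compressed when `gzip = TRUE`
#'   (the default, matching archive distribution practice).
#' @param gzip compress the output.
#' @return the path, invisibly.
#' @export
writeMmcif <- function(doc, path, gzip = TRUE) {
    lines <- c(paste0("data_", doc@entryId), "#")
    for (tb in doc@tables) {
        nrow <- if (length(tb$data)) length(tb$data[[1L]]) else 0L
        if (tb$loop || nrow > 1L) {
            hdr <- paste0(tb$category, ".", tb$items)
            body <- if (nrow) {
                cols <- lapply(tb$data, formatCifValue)
                padded <- lapply(cols, function(x) {
                    ml <- grepl("\n", x, fixed = TRUE)
                    w <- max(nchar(x[!ml]), 1L)
                    x[!ml] <- formatC(x[!ml], width = -w)
                    x
                })
                sub("[ \t]+$", "", do.call(paste, padded))
            } else character()
            lines <- c(lines, "loop_", hdr, body, "#")
        } else {
            tags <- paste0(tb$category, ".", tb$items)
            w <- max(nchar(tags)) + 3L
            vals <- formatCifValue(vapply(tb$data, `[[`, "", 1L))
            lines <- c(lines, paste0(formatC(tags, width = -w), vals), "#")
        }
    }
    # multi-line values were embedded with leading newlines; expand them
    lines <- unlist(strsplit(lines, "\n", fixed = TRUE), use.names = FALSE)
    con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Access the tables of an mmCIF document
#'
#' `cifCategories` lists category names in file order; `cifTable` returns the
#' first table of a category as a data.frame of character columns;
#' `cifTable<-` replaces it (the replacement must keep the same column set).
#'
#' @param doc an [MmcifDocument-class].
#' @param category a category name such as `"_atom_site"`.
#' @param value replacement data.frame of character columns.
#' @return `cifTable` returns a data.frame, or `NULL` when absent.
#' @export
cifCategories <- function(doc)
    vapply(doc@tables, `[[`, "", "category")

#' @rdname cifCategories
#' @export
cifTable <- function(doc, category) {
    for (tb in doc@tables)
        if (tb$category == category)
            return(data.frame(tb$data, stringsAsFactors = FALSE,
                              check.names = FALSE))
    NULL
}

#' @rdname cifCategories
#' @export
`cifTable<-` <- function(doc, category, value) {
    for (i in seq_along(doc@tables)) {
        if (doc@tables[[i]]$category == category) {
            stopifnot(identical(sort(names(value)),
                                sort(doc@tables[[i]]$items)))
            doc@tables[[i]]$data <-
                lapply(stats::setNames(doc@tables[[i]]$items,
                                       doc@tables[[i]]$items),
                       function(it) as.character(value[[it]]))
            return(doc)
        }
    }
    stop("no table ", sQuote(category), " in document", call. = FALSE)
}

#' Output file name for a renumbered entry
#'
#' Renumbered files carry the `_renum` name tag: `2aa3_renum.cif.gz`,
#' `2aa3_renum.pdb`, assemblies `2aa3-assembly-1_renum.cif.gz` (mmCIF) or
#' `2aa3_renum.pdb1.gz` (legacy).
#'
#' @param id 4-character entry id.
#' @param format `"mmcif"` or `"legacy"`.
#' @param gzip whether the output is compressed.
#' @param assembly assembly number, or `NA` for the asymmetric unit.
#' @return file name (no directory).
#' @examples
#' renumFileName("2aa3", "mmcif")
#' renumFileName("2aa3", "legacy", gzip = FALSE)
#' @export
renumFileName <- function(id, format = c("mmcif", "legacy"), gzip = TRUE,
                          assembly = NA) {
    format <- match.arg(format)
    base <- if (format == "mmcif") {
        if (is.na(assembly)) sprintf("%s_renum.cif", id)
        else sprintf("%s-assembly-%d_renum.cif", id, as.integer(assembly))
    } else {
        if (is.na(assembly)) sprintf("%s_renum.pdb", id)
        else sprintf("%s_renum.pdb%d", id, as.integer(assembly))
    }
    if (gzip) paste0(base, ".gz") else base
}
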