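# Minimal generic PDBx/mmCIF category reader.
#
# Parses data blocks into named lists of character tibbles, one tibble per
# category (e.g. "atom_site", "chem_comp_bond"), one column per item.  Handles
# loop_ constructs, single key-value pairs, quoted values and semicolon text
# blocks, which is the full dialect range the atom_site and chem_comp
# categories of structure models and component dictionaries use.

cif_tokenize <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1L) return(character())
  toks <- regmatches(line, list(m))[[1]]
  # a token starting with '#' opens a comment: drop it and the rest
  cm <- which(startsWith(toks, "#"))
  if (length(cm)) toks <- toks[seq_len(cm[1] - 1L)]
  # strip paired quotes
  q <- grepl("^'.*'$|^\".*\"$", toks)
  toks[q] <- substr(toks[q], 2L, nchar(toks[q]) - 1L)
  toks
}

cif_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  block_name <- NULL
  cats <- list() # category -> list(items = chr, values = chr)

  flush_block <- function() {
    if (is.null(block_name)) return()
    out <- lapply(cats, function(cc) {
      nv <- length(cc$values)
      ni <- length(cc$items)
      if (nv %% ni != 0L) {
        abort(sprintf(
          "mmCIF parse error in '%s': category '%s' has %d values for %d items",
          path, cc$name, nv, ni))
      }
      m <- matrix(cc$values, ncol = ni, byrow = TRUE)
      colnames(m) <- cc$items
      as_tibble(m)
    })
    blocks[[block_name]] <<- out
    cats <<- list()
  }

  i <- 1L
  n <- length(lines)
  next_values <- function(i) {
    # collect value tokens starting at line i until a reserved word / item tag
    vals <- character()
    while (i <= n) {
      ln <- lines[i]
      if (startsWith(ln, ";")) { # semicolon text block
        txt <- sub("^;", "", ln)
        i <- i + 1L
        while (i <= n && !startsWith(lines[i], ";")) {
          txt <- paste(txt, lines[i], sep = "\n")
          i <- i + 1L
        }
        if (i > n) abort(sprintf("mmCIF parse error in '%s': unterminated text block", path))
        vals <- c(vals, txt)
        i <- i + 1L
        next
      }
      toks <- cif_tokenize(ln)
      if (length(toks) == 0L) { i <- i + 1L; next }
      if (grepl("^(_|loop_$|data_|stop_$|save_)", toks[1])) break
      vals <- c(vals, toks)
      i <- i + 1L
    }
    list(values = vals, i = i)
  }

  while (i <= n) {
    toks <- cif_tokenize(lines[i])
    if (length(toks) == 0L) { i <- i + 1L; next }
    t1 <- toks[1]
    if (startsWith(t1, "data_")) {
      flush_block()
      block_name <- sub("^data_", "", t1)
      if (block_name == "") block_name <- "unnamed"
      i <- i + 1L
    } else if (identical(t1, "loop_")) {
      i <- i + 1L
      items <- character()
      while (i <= n) {
        tk <- cif_tokenize(lines[i])
        if (length(tk) && startsWith(tk[1], "_")) {
          items <- c(items, tk[1])
          i <- i + 1L
        } else break
      }
      if (!length(items)) abort(sprintf("mmCIF parse error in '%s': loop_ without items near line %d", path, i))
      nv <- next_values(i)
      i <- nv$i
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", items[1])
      item_names <- sub("^_[^.]+\\.", "", items)
      prev <- cats[[cat_name]]
      if (is.null(prev)) {
        cats[[cat_name]] <- list(name = cat_name, items = item_names, values = nv$values)
      } else {
        abort(sprintf("mmCIF parse error in '%s': duplicate category '%s'", path, cat_name))
      }
    } else if (startsWith(t1, "_")) {
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", t1)
      item_name <- sub("^_[^.]+\\.", "", t1)
      if (length(toks) >= 2L) {
        val <- toks[2]
        i <- i + 1L
      } else {
        nv <- next_values(i + 1L)
        if (!length(nv$values)) abort(sprintf("mmCIF parse error in '%s': item '%s' has no value", path, t1))
        val <- nv$values[1]
        i <- nv$i
      }
      prev <- cats[[cat_name]]
      if (is.null(prev)) {
        cats[[cat_name]] <- list(name = cat_name, items = item_name, values = val)
      } else {
        cats[[cat_name]]$items <- c(prev$items, item_name)
        cats[[cat_name]]$values <- c(prev$values, val)
      }
    } else {
      i <- i + 1L # stray token outside any construct; tolerate
    }
  }
  if (is.null(block_name)) abort(sprintf("mmCIF parse error in '%s': no data block found", path))
  flush_block()
  blocks
}

# pick the first item present among `candidates`; NA column otherwise
cif_col <- function(tbl, candidates, default = NA_character_) {
  for (cand in candidates) {
    if (cand %in% names(tbl)) return(tbl[[cand]])
  }
  rep(default, nrow(tbl))
}

cif_clean <- function(x) {
  x[x %in% c(".", "?")] <- NA_character_
  x
}

cif_num <- function(x) suppressWarnings(as.numeric(cif_clean(x)))
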