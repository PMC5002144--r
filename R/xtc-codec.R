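# Gromacs XTC coordinate compression: bounded integer quantization with
# variable-bit-width packing and run-length encoding of small inter-atom
# deltas ("smallidx" scheme). Bit-exact port of the xdr3dfcoord layout;
# arithmetic is done in doubles (exact below 2^53) to avoid 32-bit overflow.

XTC_MAGICINTS <- c(
  0, 0, 0, 0, 0, 0, 0, 0, 0, 8, 10, 12, 16, 20, 25, 32, 40, 50, 64,
  80, 101, 128, 161, 203, 256, 322, 406, 512, 645, 812, 1024, 1290,
  1625, 2048, 2580, 3250, 4096, 5060, 6501, 8192, 10321, 13003,
  16384, 20642, 26007, 32768, 41285, 52015, 65536, 82570, 104031,
  131072, 165140, 208063, 262144, 330280, 416127, 524287, 660561,
  832255, 1048576, 1321122, 1664510, 2097152, 2642245, 3329021,
  4194304, 5284491, 6658042, 8388607, 10568983, 13316085, 16777216)
XTC_FIRSTIDX <- 10L  # 1-based: XTC_MAGICINTS[10] == 8 (C index 9)
XTC_LASTIDX <- length(XTC_MAGICINTS)  # 73 (C LASTIDX, 1-based)

# smallest n with 2^n >= size (n >= 1 even for size 1, as in the reference)
xtc_sizeofint <- function(size) {
  num <- 1; nbits <- 0L
  while (size >= num && nbits < 32L) { nbits <- nbits + 1L; num <- num * 2 }
  nbits
}

xtc_sizeofints <- function(sizes) {
  bytes <- 1; nb <- 1L
  for (s in sizes) {
    tmp <- 0
    for (k in seq_len(nb)) {
      tmp <- bytes[k] * s + tmp
      bytes[k] <- tmp %% 256
      tmp <- tmp %/% 256
    }
    while (tmp != 0) {
      nb <- nb + 1L
      bytes[nb] <- tmp %% 256
      tmp <- tmp %/% 256
    }
  }
  num <- 1; nbits <- 0L
  while (bytes[nb] >= num) { nbits <- nbits + 1L; num <- num * 2 }
  nbits + (nb - 1L) * 8L
}

# --- bit writer ------------------------------------------------------------
new_bitwriter <- function(capacity = 4096L) {
  e <- new.env(parent = emptyenv())
  e$buf <- integer(capacity); e$cnt <- 0L; e$lastbits <- 0L; e$lastbyte <- 0
  e
}

bw_put_byte <- function(e, b) {
  if (e$cnt >= length(e$buf)) e$buf <- c(e$buf, integer(length(e$buf)))
  e$cnt <- e$cnt + 1L
  e$buf[e$cnt] <- as.integer(b)
}

bw_bits <- function(e, nbits, num) {
  num <- num %% 2^nbits
  lastbyte <- e$lastbyte; lastbits <- e$lastbits
  while (nbits >= 8L) {
    lastbyte <- (lastbyte * 256 + (num %/% 2^(nbits - 8L))) %% 2^24
    bw_put_byte(e, (lastbyte %/% 2^lastbits) %% 256)
    nbits <- nbits - 8L
    num <- num %% 2^nbits  # strip the 8 bits just written
  }
  if (nbits > 0L) {
    lastbyte <- (lastbyte * 2^nbits + (num %% 2^nbits)) %% 2^24
    lastbits <- lastbits + nbits
    if (lastbits >= 8L) {
      lastbits <- lastbits - 8L
      bw_put_byte(e, (lastbyte %/% 2^lastbits) %% 256)
    }
  }
  e$lastbyte <- lastbyte; e$lastbits <- lastbits
  invisible(e)
}

bw_ints <- function(e, nbits, sizes, nums) {
  bytes <- numeric(0)
  tmp <- nums[1L]
  repeat {
    bytes[length(bytes) + 1L] <- tmp %% 256
    tmp <- tmp %/% 256
    if (tmp == 0) break
  }
  for (i in 2:3) {
    if (nums[i] >= sizes[i])
      stop("xtc codec internal error: value exceeds its size bound")
    tmp <- nums[i]
    for (k in seq_along(bytes)) {
      tmp <- bytes[k] * sizes[i] + tmp
      bytes[k] <- tmp %% 256
      tmp <- tmp %/% 256
    }
    while (tmp != 0) {
      bytes[length(bytes) + 1L] <- tmp %% 256
      tmp <- tmp %/% 256
    }
  }
  nb <- length(bytes)
  if (nbits >= nb * 8L) {
    for (k in seq_len(nb)) bw_bits(e, 8L, bytes[k])
    bw_bits(e, nbits - nb * 8L, 0)
  } else {
    for (k in seq_len(nb - 1L)) bw_bits(e, 8L, bytes[k])
    bw_bits(e, nbits - (nb - 1L) * 8L, bytes[nb])
  }
  invisible(e)
}

bw_finish <- function(e) {
  n <- e$cnt
  out <- e$buf[seq_len(n)]
  if (e$lastbits > 0L)
    out <- c(out, as.integer((e$lastbyte * 2^(8L - e$lastbits)) %% 256))
  as.raw(out)
}

# --- bit reader ------------------------------------------------------------
new_bitreader <- function(bytes) {
  e <- new.env(parent = emptyenv())
  e$bytes <- as.integer(bytes); e$cnt <- 0L; e$lastbits <- 0L; e$lastbyte <- 0
  e
}

br_next_byte <- function(e) {
  e$cnt <- e$cnt + 1L
  if (e$cnt > length(e$bytes)) stop("xtc bit-stream exhausted (corrupt frame)")
  e$bytes[e$cnt]
}

br_bits <- function(e, nbits) {
  num <- 0
  lastbyte <- e$lastbyte; lastbits <- e$lastbits
  total <- nbits
  while (nbits >= 8L) {
    lastbyte <- (lastbyte * 256 + br_next_byte(e)) %% 2^24
    num <- num + ((lastbyte %/% 2^lastbits) %% 256) * 2^(nbits - 8L)
    nbits <- nbits - 8L
  }
  if (nbits > 0L) {
    if (lastbits < nbits) {
      lastbits <- lastbits + 8L
      lastbyte <- (lastbyte * 256 + br_next_byte(e)) %% 2^24
    }
    lastbits <- lastbits - nbits
    num <- num + (lastbyte %/% 2^lastbits) %% 2^nbits
  }
  num <- num %% 2^total
  e$lastbyte <- lastbyte; e$lastbits <- lastbits
  num
}

br_ints <- function(e, nbits, sizes) {
  bytes <- numeric(0)
  while (nbits > 8L) {
    bytes[length(bytes) + 1L] <- br_bits(e, 8L)
    nbits <- nbits - 8L
  }
  if (nbits > 0L) bytes[length(bytes) + 1L] <- br_bits(e, nbits)
  nums <- numeric(3)
  for (i in 3:2) {
    num <- 0
    for (j in rev(seq_along(bytes))) {
      num <- num * 256 + bytes[j]
      p <- num %/% sizes[i]
      bytes[j] <- p
      num <- num - p * sizes[i]
    }
    nums[i] <- num
  }
  b <- c(bytes, 0, 0, 0, 0)
  nums[1L] <- b[1L] + b[2L] * 256 + b[3L] * 65536 + b[4L] * 16777216
  nums
}

# --- frame coordinate block ------------------------------------------------

# Encode an n x 3 coordinate matrix (nm) at the given precision.
# Returns the raw bytes of the compressed block *after* the leading
# natoms/precision words (i.e. minint..data, unpadded).
xtc_encode_coords <- function(xyz, precision) {
  n <- nrow(xyz)
  stopifnot(n > 9L)
  lint <- matrix(0, n, 3L)
  lf <- xyz * precision
  lint <- trunc(lf + 0.5 * sign_pos(lf))
  if (any(abs(lint) > .Machine$integer.max - 2))
    stop("coordinate overflow at this precision")
  minint <- apply(lint, 2L, min)
  maxint <- apply(lint, 2L, max)
  d <- abs(lint[-1L, , drop = FALSE] - lint[-n, , drop = FALSE])
  mindiff <- if (n > 1L) min(rowSums(d)) else .Machine$integer.max
  sizeint <- maxint - minint + 1
  if (any(sizeint > 16777215)) {
    bitsizeint <- vapply(sizeint, xtc_sizeofint, 0L)
    bitsize <- 0L
  } else {
    bitsizeint <- integer(3)
    bitsize <- xtc_sizeofints(sizeint)
  }
  smallidx <- XTC_FIRSTIDX
  while (smallidx < XTC_LASTIDX && XTC_MAGICINTS[smallidx] < mindiff)
    smallidx <- smallidx + 1L
  smallidx0 <- smallidx  # header value; the working copy adapts per run
  maxidx <- min(XTC_LASTIDX, smallidx + 8L)
  minidx <- maxidx - 8L
  smaller <- XTC_MAGICINTS[max(XTC_FIRSTIDX, smallidx - 1L)] %/% 2
  smallnum <- XTC_MAGICINTS[smallidx] %/% 2
  sizesmall <- rep(XTC_MAGICINTS[smallidx], 3L)
  larger <- XTC_MAGICINTS[maxidx] %/% 2
  bw <- new_bitwriter(max(1024L, n * 6L))
  co <- t(lint)  # column-per-atom for fast [ , i] access
  dim(co) <- NULL  # flat like the C int buffer: x1 y1 z1 x2 ...
  i <- 0L
  prevrun <- -1L
  prevcoord <- c(0, 0, 0)
  while (i < n) {
    is_small <- 0L
    base <- i * 3L
    this <- co[(base + 1L):(base + 3L)]
    if (smallidx < maxidx && i >= 1L &&
        all(abs(this - prevcoord) < larger)) {
      is_smaller <- 1L
    } else if (smallidx > minidx) {
      is_smaller <- -1L
    } else is_smaller <- 0L
    if (i + 1L < n) {
      nxt <- co[(base + 4L):(base + 6L)]
      if (all(abs(this - nxt) < smallnum)) {
        co[(base + 1L):(base + 3L)] <- nxt
        co[(base + 4L):(base + 6L)] <- this
        this <- nxt
        is_small <- 1L
      }
    }
    tmpc <- this - minint
    if (bitsize == 0L) {
      bw_bits(bw, bitsizeint[1L], tmpc[1L])
      bw_bits(bw, bitsizeint[2L], tmpc[2L])
      bw_bits(bw, bitsizeint[3L], tmpc[3L])
    } else {
      bw_ints(bw, bitsize, sizeint, tmpc)
    }
    prevcoord <- this
    i <- i + 1L
    run <- 0L
    runvals <- numeric(0)
    if (is_small == 0L && is_smaller == -1L) is_smaller <- 0L
    while (is_small && run < 24L) {
      base <- i * 3L
      this <- co[(base + 1L):(base + 3L)]
      if (is_smaller == -1L && sum((this - prevcoord)^2) >= smaller * smaller)
        is_smaller <- 0L
      runvals <- c(runvals, this - prevcoord + smallnum)
      run <- run + 3L
      prevcoord <- this
      i <- i + 1L
      is_small <- 0L
      if (i < n) {
        nxt <- co[(i * 3L + 1L):(i * 3L + 3L)]
        if (all(abs(nxt - prevcoord) < smallnum)) is_small <- 1L
      }
    }
    if (run != prevrun || is_smaller != 0L) {
      prevrun <- run
      bw_bits(bw, 1L, 1)
      bw_bits(bw, 5L, run + is_smaller + 1L)
    } else {
      bw_bits(bw, 1L, 0)
    }
    for (k in seq_len(run %/% 3L))   # bit width is the 0-based magic index
      bw_ints(bw, smallidx - 1L, sizesmall, runvals[(3L * k - 2L):(3L * k)])
    if (is_smaller != 0L) {
      smallidx <- smallidx + is_smaller
      if (is_smaller < 0L) {
        smallnum <- smaller
        smaller <- XTC_MAGICINTS[smallidx - 1L] %/% 2
      } else {
        smaller <- smallnum
        smallnum <- XTC_MAGICINTS[smallidx] %/% 2
      }
      sizesmall <- rep(XTC_MAGICINTS[smallidx], 3L)
    }
  }
  list(minint = minint, maxint = maxint, smallidx = smallidx0,
       data = bw_finish(bw))
}

sign_pos <- function(x) ifelse(x >= 0, 1, -1)

# Decode a compressed coordinate block back to an n x 3 matrix (nm).
xtc_decode_coords <- function(n, precision, minint, maxint, smallidx, data) {
  sizeint <- maxint - minint + 1
  if (any(sizeint > 16777215)) {
    bitsizeint <- vapply(sizeint, xtc_sizeofint, 0L)
    bitsize <- 0L
  } else {
    bitsizeint <- integer(3)
    bitsize <- xtc_sizeofints(sizeint)
  }
  if (smallidx < XTC_FIRSTIDX || smallidx > XTC_LASTIDX)
    stop("corrupt xtc frame: smallidx out of range")
  maxidx <- min(XTC_LASTIDX, smallidx + 8L)
  minidx <- maxidx - 8L
  smaller <- XTC_MAGICINTS[max(XTC_FIRSTIDX, smallidx - 1L)] %/% 2
  smallnum <- XTC_MAGICINTS[smallidx] %/% 2
  sizesmall <- rep(XTC_MAGICINTS[smallidx], 3L)
  br <- new_bitreader(data)
  out <- numeric(n * 3L)
  op <- 0L
  inv <- 1 / precision
  i <- 0L
  run <- 0L
  while (i < n) {
    if (bitsize == 0L) {
      this <- c(br_bits(br, bitsizeint[1L]), br_bits(br, bitsizeint[2L]),
                br_bits(br, bitsizeint[3L]))
    } else {
      this <- br_ints(br, bitsize, sizeint)
    }
    i <- i + 1L
    this <- this + minint
    prevcoord <- this
    flag <- br_bits(br, 1L)
    is_smaller <- 0L
    if (flag == 1) {
      run <- as.integer(br_bits(br, 5L))
      is_smaller <- run %% 3L
      run <- run - is_smaller
      is_smaller <- is_smaller - 1L
    }
    if (op + run * 1L + 3L > n * 3L + 3L && run > 0L)
      stop("corrupt xtc frame: run overflows atom count")
    if (run > 0L) {
      for (k in seq(0L, run - 1L, by = 3L)) {
        sm <- br_ints(br, smallidx - 1L, sizesmall)
        i <- i + 1L
        sm <- sm + prevcoord - smallnum
        if (k == 0L) {
          tmp <- sm; sm <- prevcoord; prevcoord <- tmp
          out[(op + 1L):(op + 3L)] <- prevcoord * inv
          op <- op + 3L
        } else {
          prevcoord <- sm
        }
        out[(op + 1L):(op + 3L)] <- sm * inv
        op <- op + 3L
      }
    } else {
      out[(op + 1L):(op + 3L)] <- this * inv
      op <- op + 3L
    }
    smallidx <- smallidx + is_smaller
    if (is_smaller < 0L) {
      smallnum <- smaller
      smaller <- if (smallidx > XTC_FIRSTIDX)
        XTC_MAGICINTS[smallidx - 1L] %/% 2 else 0
    } else if (is_smaller > 0L) {
      smaller <- smallnum
      smallnum <- XTC_MAGICINTS[smallidx] %/% 2
    }
    if (smallidx < 1L || smallidx > XTC_LASTIDX ||
        XTC_MAGICINTS[smallidx] == 0)
      stop("corrupt xtc frame: invalid small-integer state")
    sizesmall <- rep(XTC_MAGICINTS[smallidx], 3L)
  }
  matrix(out, ncol = 3L, byrow = TRUE)
}
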