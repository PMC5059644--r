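test_that("the published protocol entries are honored verbatim", {
  proto <- build_default_protocol(seed = 1)
  expect_equal(char_to_motions("a", proto),
               c("up", "down", "up", "center"))
  expect_equal(char_to_motions("ko", proto),
               c("up", "center", "up", "center"))
  expect_equal(char_to_motions("e", proto),
               c("up", "left", "up", "center"))
  expect_equal(char_to_motions("ka", proto),
               c("up", "left", "right", "center"))
  expect_equal(char_to_motions("ga", proto),
               c("right", "left", "down", "center",
                 "up", "left", "right", "center"))
  expect_error(char_to_motions("zz", proto), "unknown character")
})

test_that("the default protocol has 48 distinct valid basic codes", {
  proto <- build_default_protocol(seed = 1)
  expect_length(proto$basic, 48)
  expect_length(proto$marks, 2)
  codes <- proto$table[proto$basic]
  expect_true(all(lengths(codes) == 4))
  expect_equal(anyDuplicated(vapply(codes, paste, "", collapse = ",")), 0L)
  for (code in proto$table) validate_motion_sequence(code)
  # deterministic given seed
  expect_identical(build_default_protocol(seed = 9)$table,
                   build_default_protocol(seed = 9)$table)
})

test_that("word expansion concatenates codes and flags bad boundaries", {
  proto <- build_default_protocol(seed = 1)
  expect_length(word_to_motions(c("a", "ko"), proto), 8)
  expect_identical(word_to_motions(character(0), proto), character(0))
  # construct a synthetic protocol whose concatenation repeats a motion
  bad <- proto
  bad$table$zz <- c("center", "up", "down", "center")
  bad$basic <- c(bad$basic, "zz")
  expect_error(word_to_motions(c("a", "zz"), bad),
               "boundary between 'a' and 'zz'")
})

test_that("random words decode back through greedy framing", {
  proto <- build_default_protocol(seed = 2)
  chars <- c(proto$basic, proto$derived)
  set.seed(11)
  for (i in 1:25) {
    word <- sample(chars, sample(1:5, 1), replace = TRUE)
    motions <- word_to_motions(word, proto)
    expect_identical(motions_to_chars(motions, proto), word)
  }
  expect_error(motions_to_chars(c("up", "down"), proto), "multiple of 4")
})

test_that("protocol TSV round-trips and validates", {
  proto <- build_default_protocol(seed = 1)
  expect_true(roundtrip_check(proto))
  path <- tempfile(fileext = ".tsv")
  write_protocol(proto, path)
  reread <- read_protocol(path)
  expect_identical(proto$table[["ga"]], reread$table[["ga"]])
  # validation catches corrupted codes
  lines <- readLines(path)
  lines[2] <- sub("\t[a-z]+,", "\tup,up,", lines[2])
  writeLines(lines, path)
  expect_error(read_protocol(path))
})

test_that("there are 320 valid 4-motion codes over 5 motions", {
  # 5 * 4 * 4 * 4 with no adjacent repeats; the protocol only needs 50
  ab <- motion_alphabet()
  n <- 0L
  for (m1 in ab) for (m2 in setdiff(ab, m1))
    for (m3 in setdiff(ab, m2)) for (m4 in setdiff(ab, m3)) n <- n + 1L
  expect_equal(n, 320L)
})
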