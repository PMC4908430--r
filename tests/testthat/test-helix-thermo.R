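params <- nn_param_table()

test_that("the bundled parameter table is complete and symmetric", {
  expect_s3_class(params, "nn_param_table")
  expect_length(params$stacks, 36)   # every ordered WC/GU step
  expect_true(params$init > 0)
  expect_true(all(params$stacks[c("GG/CC", "GC/CG", "CC/GG")] < -1))
  expect_true(all(c("3", "4", "30") %in% names(params$hairpin_loop)))
})

test_that("a 1-bp duplex has only initiation and terminal terms", {
  gc <- helix_duplex("G", "C")
  expect_equal(helix_dG37(gc, params), params$init)
  au <- helix_duplex("A", "U")
  expect_equal(helix_dG37(au, params), params$init + 2 * params$terminal_au)
})

test_that("a 4-bp helix sums initiation, three stacks and end penalties", {
  # 5'-AGCU-3' / 3'-UCGA-5': pairs A-U, G-C, C-G, U-A; steps AG/UC, GC/CG,
  # CU/GA. Hand-summed from the bundled table (Turner 2004 / ViennaRNA):
  #   4.10 + (-2.10) + (-3.40) + (-2.10) + 0.50 + 0.50 = -2.50
  h <- helix_duplex("AGCU", "AGCU")
  expect_equal(helix_dG37(h, params), -2.50, tolerance = 1e-9)
  st <- params$stacks
  manual <- params$init + st[["AG/UC"]] + st[["GC/CG"]] + st[["CU/GA"]] +
    2 * params$terminal_au
  expect_equal(helix_dG37(h, params), manual, tolerance = 1e-12)
})

test_that("appending a G-C pair strictly stabilizes any helix", {
  for (s in list(c("GCAU", "AUGC"), c("AAAA", "UUUU"), c("GGGG", "CCCC"))) {
    base <- helix_duplex(s[1], s[2])
    ext <- helix_duplex(paste0(s[1], "G"), paste0("C", s[2]))
    expect_lt(helix_dG37(ext, params), helix_dG37(base, params))
  }
})

test_that("energy is invariant under strand flip", {
  for (s in list(c("GCAU", "AUGC"), c("GGUC", "GGCC"), c("AGCU", "AGCU"))) {
    h <- helix_duplex(s[1], s[2])
    flipped <- helix_duplex(s[2], s[1])
    expect_equal(helix_dG37(flipped, params), helix_dG37(h, params),
                 tolerance = 1e-12)
  }
})

test_that("extension by one pair adds exactly one stack term", {
  base <- helix_duplex("GCA", "UGC")      # G-C, C-G, A-U
  ext <- helix_duplex("GCAG", "CUGC")     # append G-C below the A-U end
  dG_base <- helix_dG37(base, params)
  dG_ext <- helix_dG37(ext, params)
  # bookkeeping: add the AG/UC stack, drop the A-U terminal penalty
  expect_equal(dG_ext - dG_base,
               params$stacks[["AG/UC"]] - params$terminal_au,
               tolerance = 1e-12)
})

test_that("hairpin capping adds the loop penalty for its length", {
  h_open <- helix_duplex("GGCC", "GGCC")
  h_cap <- helix_duplex("GGCC", "GGCC", closing_loop = 4)
  expect_equal(helix_dG37(h_cap, params) - helix_dG37(h_open, params),
               params$hairpin_loop[["4"]], tolerance = 1e-12)
  expect_error(helix_duplex("GGCC", "GGCC", closing_loop = 2), "forbidden")
})

test_that("mismatched appositions and bad alphabets are rejected", {
  expect_error(helix_duplex("GACC", "GGCC"), "not a Watson-Crick or G.U pair")
  expect_error(helix_duplex("GGC", "GGCC"), "lengths differ")
  expect_error(helix_duplex("GGXC", "GGCC"), "non-RNA")
  expect_warning(h <- helix_duplex("GGTC", "GACC"), "T normalized to U")
  expect_equal(h$strand5, "GGUC")
})

test_that("wobble pairs are accepted", {
  h <- helix_duplex("GGUC", "GGCC")  # includes a G.U apposition
  expect_s3_class(h, "helix_duplex")
  expect_true(is.finite(helix_dG37(h, params)))
})

test_that("information content is 2 bits per base pair", {
  expect_identical(info_bits(0), 0)
  expect_identical(info_bits(5), 10)
  expect_identical(info_bits(7), 14)
  expect_equal(info_bits(3) + info_bits(4), info_bits(7))
  expect_error(info_bits(-1), "non-negative")
})

test_that("FASTA parsing handles paired-record and hairpin dialects", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">c1 strand5", "GGCAUC",
    ">c1 strand3", "GAUGCC",
    ">c2 loop=4", paste0("GGCC", "GAAA", "GGCC")
  ), fa)
  duplexes <- parse_construct_fasta(fa)
  expect_length(duplexes, 2)
  expect_equal(duplexes[[1]]$n_bp, 6)
  expect_identical(duplexes[[1]]$id, "c1")
  expect_equal(duplexes[[2]]$n_bp, 4)
  expect_equal(duplexes[[2]]$closing_loop, 4L)

  # T-containing input is normalized with a warning
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">t strand5", "GGTC", ">t strand3", "GACC"), fa2)
  expect_warning(d2 <- parse_construct_fasta(fa2), "T normalized to U")
  expect_equal(d2[[1]]$strand5, "GGUC")

  # non-pairing apposition fails validation
  fa3 <- tempfile(fileext = ".fasta")
  writeLines(c(">bad strand5", "GACC", ">bad strand3", "GGCC"), fa3)
  expect_error(parse_construct_fasta(fa3), "not a Watson-Crick")
})
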