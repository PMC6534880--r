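test_that("tokenizer splits multi-character units and stays lossless", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_smiles("C(Cl)Br"), c("C", "(", "Cl", ")", "Br"))
  expect_identical(tokenize_smiles("c1ccccc1"),
                   c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(tokenize_smiles("[nH]1[C@@H]%12"),
                   c("[nH]", "1", "[C@@H]", "%12"))
  # lossless re-join across a varied corpus
  cases <- c(toy_corpus()[1:200], "CC(=O)Nc1ccc(O)cc1", "C%11CC%11",
             "O=C(O)/C=C\\C(=O)O", "[O-][N+](=O)c1ccccc1Cl")
  for (s in cases)
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
})

test_that("tokenizer rejects malformed input", {
  expect_error(tokenize_smiles("CCx"), "cannot start")
  expect_error(tokenize_smiles("C[NH"), "unterminated bracket")
  expect_error(tokenize_smiles("C%1C"), "malformed")
  expect_error(tokenize_smiles(""))
})

test_that("vocabulary is the token union plus controls, deterministically ordered", {
  v <- build_vocabulary(c("CCO", "CCN"))
  expect_s3_class(v, "smiles_vocab")
  expect_identical(v$tokens, c("GO", "EOS", "C", "N", "O"))
  expect_length(v, 5L)
  expect_identical(unname(v$index[v$tokens]), seq_len(5L))
  # idempotent and order-independent
  expect_identical(build_vocabulary(c("CCN", "CCO")), v)
  expect_identical(build_vocabulary(c("C", "C")),
                   build_vocabulary("C"))
  expect_error(build_vocabulary(character(0)), "empty corpus")
})

test_that("encode/decode round-trips and strips control tokens", {
  v <- toy_vocab()
  for (s in toy_corpus()[seq(1, 400, by = 7)])
    expect_identical(decode_tokens(encode_smiles(s, v), v), s)
  v5 <- build_vocabulary(c("CCO", "CCN"))
  enc <- encode_smiles("CCO", v5)
  expect_length(enc, 3L)
  expect_false(any(enc %in% c(v5$index[["GO"]], v5$index[["EOS"]])))
  expect_identical(decode_tokens(c(v5$index[["GO"]], v5$index[["C"]],
                                   v5$index[["EOS"]]), v5), "C")
  expect_error(encode_smiles("CBr", v5), "Br")
  expect_error(decode_tokens(c(1L, 99L), v5), "out of vocabulary")
})

test_that("vocabulary file round-trips", {
  v <- toy_vocab()
  path <- withr::local_tempfile()
  write_vocabulary(v, path)
  expect_identical(read_vocabulary(path), v)
})

test_that("is_valid_smiles matches the RDKit parser criterion", {
  expect_identical(is_valid_smiles(c("CCO", "C(", "c1cc1", "", "C1CC")),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(is_valid_smiles(toy_corpus()[1:50])))
})
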