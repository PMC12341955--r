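# Sobol direction-number table (Joe-Kuo), dimensions 1..48.
# poly: primitive polynomial over GF(2) encoded as an integer;
# minit: initial odd direction integers m_1..m_s (s = polynomial degree).
.sobol_poly <- c(1, 3, 7, 11, 13, 19, 25, 37, 41, 47, 55, 59, 61, 67, 91, 97, 103, 109, 115, 131, 137, 143, 145, 157, 167, 171, 185, 191, 193, 203, 211, 213, 229, 239, 241, 247, 253, 285, 299, 301, 333, 351, 355, 357, 361, 369, 391, 397)
.sobol_minit <- list(
  c(1),
  c(1),
  c(1, 3),
  c(1, 3, 1),
  c(1, 1, 1),
  c(1, 1, 3, 3),
  c(1, 3, 5, 13),
  c(1, 1, 5, 5, 17),
  c(1, 1, 5, 5, 5),
  c(1, 1, 7, 11, 19),
  c(1, 1, 5, 1, 1),
  c(1, 1, 1, 3, 11),
  c(1, 3, 5, 5, 31),
  c(1, 3, 3, 9, 7, 49),
  c(1, 1, 1, 15, 21, 21),
  c(1, 3, 1, 13, 27, 49),
  c(1, 1, 1, 15, 7, 5),
  c(1, 3, 1, 15, 13, 25),
  c(1, 1, 5, 5, 19, 61),
  c(1, 3, 7, 11, 23, 15, 103),
  c(1, 3, 7, 13, 13, 15, 69),
  c(1, 1, 3, 13, 7, 35, 63),
  c(1, 3, 5, 9, 1, 25, 53),
  c(1, 3, 1, 13, 9, 35, 107),
  c(1, 3, 1, 5, 27, 61, 31),
  c(1, 1, 5, 11, 19, 41, 61),
  c(1, 3, 5, 3, 3, 13, 69),
  c(1, 1, 7, 13, 1, 19, 1),
  c(1, 3, 7, 5, 13, 19, 59),
  c(1, 1, 3, 9, 25, 29, 41),
  c(1, 3, 5, 13, 23, 1, 55),
  c(1, 3, 7, 3, 13, 59, 17),
  c(1, 3, 1, 3, 5, 53, 69),
  c(1, 1, 5, 5, 23, 33, 13),
  c(1, 1, 7, 7, 1, 61, 123),
  c(1, 1, 7, 9, 13, 61, 49),
  c(1, 3, 3, 5, 3, 55, 33),
  c(1, 3, 1, 15, 31, 13, 49, 245),
  c(1, 3, 5, 15, 31, 59, 63, 97),
  c(1, 3, 1, 11, 11, 11, 77, 249),
  c(1, 3, 1, 11, 27, 43, 71, 9),
  c(1, 1, 7, 15, 21, 11, 81, 45),
  c(1, 3, 7, 3, 25, 31, 65, 79),
  c(1, 3, 1, 1, 19, 11, 3, 205),
  c(1, 1, 5, 9, 19, 21, 29, 157),
  c(1, 3, 7, 11, 1, 33, 89, 185),
  c(1, 3, 3, 3, 15, 9, 79, 71),
  c(1, 3, 7, 11, 15, 39, 119, 27)
)
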