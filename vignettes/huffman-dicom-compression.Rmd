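---
title: "Lossless Huffman compression of DICOM files: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless Huffman compression of DICOM files: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huffdicom)
```

## The problem

A DICOM part-10 file bundles patient metadata and pixel data into one byte
stream: a 128-byte preamble, the ASCII magic `DICM`, tagged data elements,
and pixel data that usually dominates the file. Hospital PACS
installations store and transmit these files continuously, and any
compression applied to them must be lossless: the decompressed file has to
be bit-identical, metadata and pixels alike, because it feeds diagnosis.
This package implements whole-file static Huffman coding — a lossless,
format-agnostic byte codec — together with the measurement and viewing
tools needed to analyse how well it works on medical images.

## The model

The only statistic the codec uses is the byte frequency distribution
(BFD): the 256-entry table of occurrence counts `f(s)` over the *entire*
file. Profiling the whole stream, rather than pixel data only, is
deliberate: it needs no knowledge of DICOM structure, and it guarantees the
compressed file no longer resembles DICOM at all (see *Security* below).

Huffman construction repeatedly merges the two minimum-weight nodes until a
single prefix tree remains; a symbol's codeword is the 0/1 branch path from
the root to its leaf. The resulting code is optimal among prefix-free
codes: the encoded payload occupies

$$\text{payload\_bits} \;=\; \sum_s f(s)\,\ell(s),
\qquad nH \le \text{payload\_bits} \le n(H+1),$$

where $n$ is the file size, $\ell(s)$ the codeword length and $H$ the
empirical entropy of the BFD in bits/byte. Two consequences shape
everything downstream:

* A skewed BFD (CT images have large uniform background runs, so one byte
  value often carries well over half the file) gives $H \ll 8$ and strong
  compression.
* A near-uniform BFD gives $H \approx 8$: codewords average 8 bits or
  more, and with the container header on top the output is *larger* than
  the input (compression ratio below 1). In the limit of exactly equal
  frequencies over $2^k$ symbols every codeword has length $k$ — e.g. 8
  equal-frequency symbols, 5 occurrences each, encode to exactly
  $5 \cdot 8 \cdot 3 = 120$ bits, no better than a fixed 3-bit code, and
  256 equal-frequency byte values all receive 8-bit codewords. The package
  reports these regimes through `distribution_stats()` (entropy and
  evenness) rather than hiding them.

Both traversals of the input (tallying and encoding) are single passes, so
encoding costs $O(n)$ plus the tree work; the tree over $|\Sigma|$ symbols
has exactly $2|\Sigma|-1$ nodes (511 when all 256 byte values occur), depth
$\log_2|\Sigma|$ when balanced and up to $|\Sigma|-1$ when degenerate.

## Determinism: the tie-break rule

Huffman construction is only unique up to tie-breaking. This implementation
orders merge candidates by `(weight, lowest byte value in the subtree)` and
makes the lower-ordered node the left (0) child. Any consistent rule gives
the same codeword *lengths* (hence identical compression); this one makes
the exact codewords reproducible across runs and platforms, which the test
suite relies on. Published codeword tables produced by other
implementations are therefore comparable only in their length multisets,
never string-for-string.

## The container format

A `.huf` file is a fixed 270-byte header followed by the payload:

| field | bytes | content |
|---|---|---|
| magic | 4 | `HUF1` |
| version | 1 | `0x01` |
| original_length | 8 | unsigned little-endian |
| code lengths | 256 | canonical codeword length per byte value, 0 = absent |
| padding_bits | 1 | 0–7 |
| payload | rest | MSB-first concatenated codewords, zero-padded |

Design choices that were genuinely open:

* **Canonical lengths, not the tree.** Storing the tree or the BFD would
  work too; the 256-byte length table is the smallest header that fully
  determines a decodable code. The decoder reconstructs the canonical code
  (symbols ordered by length then value, consecutive binary codewords) —
  and the encoder uses that same canonical code, not the raw tree
  codewords, so both sides agree by construction. Canonical assignment is
  done with exact bit-vector arithmetic, so codeword lengths are not
  limited by floating-point precision.
* **Byte-boundary padding.** Payloads are padded with zero bits to the next
  8-bit boundary only (a 7-bit payload gets 1 padding bit; a 28-bit payload
  gets 4). Padding is inert because decoding terminates by symbol count,
  not by sentinel: the decoder stops after `original_length` symbols.
* **Failure behaviour without a checksum.** The header carries no checksum,
  so tampering is detected structurally instead: the magic, version and
  padding fields are validated; the length table must satisfy Kraft
  equality ($\sum 2^{-\ell} = 1$ for two or more symbols), which any
  single-byte change breaks; a declared length exceeding the payload bit
  count is rejected; and after the last symbol the decoder verifies that
  exactly all meaningful payload bits were consumed, so a corrupted
  original-length field fails loudly rather than silently returning a
  stream of the wrong length. Corrupted *payload* bits can still decode to
  wrong bytes of the right length — corruption is detected, not repaired.
* **Single-symbol inputs** get the 1-bit codeword `0` rather than 0 bits,
  keeping payload lengths well defined.

Two decoders are implemented on purpose: the production tree-walk decoder
(compiled) and an incremental-prefix reference decoder that grows the bit
thread one bit at a time and looks it up as a string. They are checked
against each other; the reference decoder is quadratic in codeword length
and intended for small inputs only.

## Security aspect

A compressed file starts `HUF1`, byte offset 128 falls inside the
code-length table (so the `DICM` magic is gone), and UID strings such as
the `1.2.840` registry prefix no longer appear in clear text.
`check_obfuscation()` verifies both properties explicitly rather than
assuming them. This is obfuscation, not encryption: anyone holding the
format specification can decompress; no confidentiality guarantee is made
or implied.

## The viewer pipeline

To demonstrate that decompressed files remain usable, a minimal "view"
path is included: `parse_dicom()` reads explicit-VR little-endian part-10
files with native (uncompressed) pixel data, `apply_window()` performs the
standard linear window level/width mapping to 8-bit grayscale, and
`resize()` does nearest-neighbour resampling. Two numerical choices the
window/resize specification leaves open: rounding is half-up (a sample
exactly at the window centre maps to 128, not 127), and resizing is
nearest-neighbour by pixel-centre mapping because it is deterministic and
exactly testable — interpolating modes would blur the
"identical before and after compression" property the tests assert.
Encapsulated transfer syntaxes, sequence elements and GUI display are out
of scope.

## Synthetic data: what it does and does not emulate

Real CT archives cannot be redistributed with a package, so all tests run
on generated inputs. `generate_bytes()` draws i.i.d. bytes from a
prescribed distribution; `generate_dicom()` wraps such bytes as the pixel
data of a minimal valid part-10 file (zero preamble, `DICM`, file-meta
group with transfer-syntax UID, image-pixel module, native pixel data).
Defaults and their rationale:

* `dominant_byte` with `dominant_fraction = 0.63` and dominant value
  `0x00`: in benchmark CT files the background byte `0x00` carries roughly
  63% of a ~1 MB file, and this regime is what makes CT compress at
  ratios around 2–3.7.
* `uniform`: the incompressible regime (entropy ≳ 7.99 bits/byte on a
  145 kB stream), reproducing qualitatively the benchmark chest image whose
  compression ratio fell just below 1.
* Pixel samples, not header bytes, carry the distribution — mirroring real
  files, where pixel data dominates the BFD.

What the generator does **not** emulate: spatial structure (real CT bytes
are highly autocorrelated; a byte-level Huffman code is insensitive to
ordering, so this does not affect compression ratios, but it means the
fixtures say nothing about codecs that exploit spatial redundancy),
modality-specific tag semantics, implicit-VR or big-endian syntaxes, and
multi-fragment pixel data. Passing tests therefore certify the codec's
losslessness, optimality and format behaviour — not clinical image quality,
which is vacuously preserved by a lossless codec.

Every generator is a pure function of its arguments and seed: the caller's
RNG state is saved and restored, and identical calls are byte-identical.

## Problem sizes in the test suite

The suite exercises round trips on over a thousand randomized streams (up
to a few hundred bytes each), DICOM fixtures of 1–15 frames at 32×32×16-bit
(the frame-count range of the benchmark inventory, scaled in pixel area),
obfuscation on 100 generated files, and Huffman optimality against an
exhaustive search over all prefix codes for alphabets of up to 6 symbols.
These sizes were chosen so the whole suite runs in well under a minute
while still covering every code path; compression behaviour itself is
size-independent (the code depends only on the BFD shape).

## Known limitations

* Ratio < 1 on near-uniform inputs is inherent to the method, not a bug;
  the reporting tools surface it rather than clamping it.
* The code is two-pass static Huffman; no adaptive or streaming variant.
* Timings reported by `batch_report()` are wall-clock and machine-dependent;
  they are recorded for context and never asserted.
* The DICOM parser covers the minimal explicit-VR little-endian surface the
  viewer needs; it is not a general DICOM toolkit.
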