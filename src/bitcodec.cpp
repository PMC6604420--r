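#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Codewords arrive as 256 "0"/"1" strings (NA = absent symbol).
// Bit order is MSB-first within each output byte.

// [[Rcpp::export]]
List encode_bits_cpp(RawVector data, CharacterVector codes) {
  if (codes.size() != 256) stop("codes must have length 256");
  std::vector<std::vector<uint8_t> > bits(256);
  std::vector<bool> present(256, false);
  for (int s = 0; s < 256; ++s) {
    if (codes[s] == NA_STRING) continue;
    std::string cw = as<std::string>(codes[s]);
    std::vector<uint8_t> b(cw.size());
    for (size_t i = 0; i < cw.size(); ++i) b[i] = (cw[i] == '1');
    bits[s] = b;
    present[s] = true;
  }

  double total_bits = 0;
  R_xlen_t n = data.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int s = data[i];
    if (!present[s]) {
      char msg[64];
      snprintf(msg, sizeof(msg), "no codeword for occurring byte value 0x%02X", s);
      stop(msg);
    }
    total_bits += bits[s].size();
  }

  R_xlen_t n_bytes = (R_xlen_t)((total_bits + 7) / 8);
  RawVector out(n_bytes);
  R_xlen_t byte_pos = 0;
  int bit_pos = 0;  // 0 = MSB
  uint8_t cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::vector<uint8_t>& b = bits[data[i]];
    for (size_t j = 0; j < b.size(); ++j) {
      if (b[j]) cur |= (uint8_t)(1 << (7 - bit_pos));
      if (++bit_pos == 8) {
        out[byte_pos++] = cur;
        cur = 0;
        bit_pos = 0;
      }
    }
  }
  if (bit_pos > 0) out[byte_pos++] = cur;  // zero padding bits already in place

  return List::create(_["payload_bytes"] = out,
                      _["payload_bits"] = total_bits);
}

// Root-to-leaf walk over an explicit decode tree built from the codewords.
// [[Rcpp::export]]
List decode_bits_cpp(RawVector payload, CharacterVector codes, double n_out) {
  if (codes.size() != 256) stop("codes must have length 256");
  // decode tree as flat arrays; node 0 is the root
  std::vector<int> left(1, -1), right(1, -1), sym(1, -1);
  for (int s = 0; s < 256; ++s) {
    if (codes[s] == NA_STRING) continue;
    std::string cw = as<std::string>(codes[s]);
    int node = 0;
    for (size_t i = 0; i < cw.size(); ++i) {
      if (sym[node] >= 0) stop("code is not prefix-free");
      std::vector<int>& child = (cw[i] == '1') ? right : left;
      if (child[node] < 0) {
        child[node] = (int)left.size();
        left.push_back(-1); right.push_back(-1); sym.push_back(-1);
      }
      node = child[node];
    }
    if (sym[node] >= 0 || left[node] >= 0 || right[node] >= 0)
      stop("code is not prefix-free");
    sym[node] = s;
  }

  R_xlen_t out_n = (R_xlen_t)n_out;
  RawVector out(out_n);
  R_xlen_t total_avail = payload.size() * 8;
  R_xlen_t bit = 0;
  for (R_xlen_t k = 0; k < out_n; ++k) {
    int node = 0;
    while (sym[node] < 0) {
      if (bit >= total_avail)
        stop("corrupted stream: bits exhausted before all symbols were decoded");
      int b = (payload[bit >> 3] >> (7 - (bit & 7))) & 1;
      ++bit;
      node = b ? right[node] : left[node];
      if (node < 0)
        stop("corrupted stream: bit thread matches no codeword");
    }
    out[k] = (uint8_t)sym[node];
  }
  return List::create(_["data"] = out, _["bits_consumed"] = (double)bit);
}
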