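// Low-level cryptographic kernel: OpenSSL BIGNUM arithmetic, prime search,
// hashing, MACs (AES-128-CMAC, HMAC-SHA-512) and AES-128-GCM.
//
// Big integers cross the R boundary as lowercase hex strings with no
// leading zeros ("0" for zero); byte strings as raw vectors.

#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/evp.h>
#include <openssl/rand.h>
#include <openssl/core_names.h>
#include <openssl/params.h>
#include <openssl/err.h>

#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct BnCtx {
  BN_CTX* ctx;
  BnCtx() : ctx(BN_CTX_new()) {
    if (!ctx) stop("BN_CTX allocation failed");
  }
  ~BnCtx() { BN_CTX_free(ctx); }
};

struct Bn {
  BIGNUM* b;
  Bn() : b(BN_new()) {
    if (!b) stop("BIGNUM allocation failed");
  }
  explicit Bn(const std::string& hex) : b(nullptr) {
    if (BN_hex2bn(&b, hex.c_str()) == 0 || b == nullptr)
      stop("invalid hex integer: '%s'", hex.c_str());
  }
  ~Bn() { BN_free(b); }
  Bn(const Bn&) = delete;
  Bn& operator=(const Bn&) = delete;
};

std::string bn_out(const BIGNUM* b) {
  char* h = BN_bn2hex(b);
  if (!h) stop("BN_bn2hex failed");
  std::string s(h);
  OPENSSL_free(h);
  for (auto& c : s) c = static_cast<char>(tolower(c));
  size_t i = 0;
  while (i + 1 < s.size() && s[i] == '0') ++i;
  return s.substr(i);
}

// small primes for trial-division sieve ahead of Miller-Rabin
const std::vector<unsigned long>& small_primes() {
  static std::vector<unsigned long> pr;
  if (pr.empty()) {
    const int N = 20000;
    std::vector<bool> comp(N + 1, false);
    for (int i = 2; i <= N; ++i) {
      if (!comp[i]) {
        pr.push_back(static_cast<unsigned long>(i));
        for (long j = static_cast<long>(i) * i; j <= N; j += i) comp[j] = true;
      }
    }
  }
  return pr;
}

bool is_prime_bn(const BIGNUM* p, BN_CTX* ctx) {
  int r = BN_check_prime(p, ctx, nullptr);
  if (r < 0) stop("primality test failed");
  return r == 1;
}

}  // namespace

// [[Rcpp::export]]
std::string cx_mod_exp(std::string base, std::string exp, std::string mod) {
  BnCtx c;
  Bn b(base), e(exp), m(mod), r;
  if (BN_is_zero(m.b)) stop("modulus is zero");
  if (!BN_mod_exp(r.b, b.b, e.b, m.b, c.ctx)) stop("mod_exp failed");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_mod_inv(std::string a, std::string mod) {
  BnCtx c;
  Bn x(a), m(mod), r;
  if (!BN_mod_inverse(r.b, x.b, m.b, c.ctx))
    stop("no modular inverse exists");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_mod(std::string a, std::string mod) {
  BnCtx c;
  Bn x(a), m(mod), r;
  if (!BN_nnmod(r.b, x.b, m.b, c.ctx)) stop("mod failed");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_mod_mul(std::string a, std::string b, std::string mod) {
  BnCtx c;
  Bn x(a), y(b), m(mod), r;
  if (!BN_mod_mul(r.b, x.b, y.b, m.b, c.ctx)) stop("mod_mul failed");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_mul(std::string a, std::string b) {
  BnCtx c;
  Bn x(a), y(b), r;
  if (!BN_mul(r.b, x.b, y.b, c.ctx)) stop("mul failed");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_add(std::string a, std::string b) {
  Bn x(a), y(b), r;
  if (!BN_add(r.b, x.b, y.b)) stop("add failed");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_sub(std::string a, std::string b) {
  Bn x(a), y(b), r;
  if (!BN_sub(r.b, x.b, y.b)) stop("sub failed");
  if (BN_is_negative(r.b)) stop("negative result not representable");
  return bn_out(r.b);
}

// [[Rcpp::export]]
std::string cx_gcd(std::string a, std::string b) {
  BnCtx c;
  Bn x(a), y(b), r;
  if (!BN_gcd(r.b, x.b, y.b, c.ctx)) stop("gcd failed");
  return bn_out(r.b);
}

// [[Rcpp::export]]
int cx_cmp(std::string a, std::string b) {
  Bn x(a), y(b);
  return BN_cmp(x.b, y.b);
}

// [[Rcpp::export]]
int cx_nbits(std::string a) {
  Bn x(a);
  return BN_num_bits(x.b);
}

// [[Rcpp::export]]
bool cx_is_prime(std::string a) {
  BnCtx c;
  Bn x(a);
  return is_prime_bn(x.b, c.ctx);
}

// Smallest prime >= start (start forced odd), found by deterministic
// incremental search: trial division by small primes, then Miller-Rabin.
// [[Rcpp::export]]
std::string cx_next_prime(std::string start) {
  BnCtx c;
  Bn p(start);
  if (BN_cmp(p.b, BN_value_one()) <= 0) stop("start must be > 1");
  if (!BN_is_odd(p.b) && !BN_is_word(p.b, 2)) BN_add_word(p.b, 1);
  const std::vector<unsigned long>& pr = small_primes();
  for (int iter = 0; iter < 1000000; ++iter) {
    bool comp = false;
    for (unsigned long q : pr) {
      BN_ULONG r = BN_mod_word(p.b, q);
      if (r == 0) { comp = BN_num_bits(p.b) > 16 || !BN_is_word(p.b, q); break; }
    }
    if (!comp && is_prime_bn(p.b, c.ctx)) return bn_out(p.b);
    BN_add_word(p.b, 2);
  }
  stop("prime search exhausted attempt budget");
}

// Smallest p >= start with both p and 2p+1 prime (a Sophie Germain prime;
// 2p+1 is the safe prime used as group modulus). Deterministic given start.
// [[Rcpp::export]]
std::string cx_next_safe_prime(std::string start) {
  BnCtx c;
  Bn p(start), q;
  if (BN_cmp(p.b, BN_value_one()) <= 0) stop("start must be > 1");
  if (!BN_is_odd(p.b)) BN_add_word(p.b, 1);
  const std::vector<unsigned long>& pr = small_primes();
  for (int iter = 0; iter < 5000000; ++iter) {
    bool comp = false;
    for (unsigned long s : pr) {
      BN_ULONG r = BN_mod_word(p.b, s);
      // reject if s divides p or divides 2p+1
      if (r == 0 || (2 * r + 1) % s == 0) { comp = true; break; }
    }
    if (!comp && is_prime_bn(p.b, c.ctx)) {
      if (!BN_lshift1(q.b, p.b)) stop("shift failed");
      BN_add_word(q.b, 1);
      if (is_prime_bn(q.b, c.ctx)) return bn_out(p.b);
    }
    BN_add_word(p.b, 2);
  }
  stop("safe-prime search exhausted attempt budget");
}

// [[Rcpp::export]]
RawVector cx_rand_bytes(int n) {
  if (n < 0) stop("n must be >= 0");
  RawVector out(n);
  if (n > 0 && RAND_bytes(RAW(out), n) != 1)
    stop("OS random generator failure");
  return out;
}

// [[Rcpp::export]]
RawVector cx_sha256(RawVector data) {
  RawVector out(32);
  unsigned int len = 32;
  if (!EVP_Digest(RAW(data), data.size(), RAW(out), &len, EVP_sha256(), nullptr))
    stop("SHA-256 failed");
  return out;
}

static RawVector mac_oneshot(const char* algo, const char* param_key,
                             const char* param_val, RawVector key,
                             RawVector msg, size_t outsz) {
  EVP_MAC* mac = EVP_MAC_fetch(nullptr, algo, nullptr);
  if (!mac) stop("MAC algorithm %s unavailable", algo);
  EVP_MAC_CTX* ctx = EVP_MAC_CTX_new(mac);
  if (!ctx) { EVP_MAC_free(mac); stop("MAC context allocation failed"); }
  OSSL_PARAM params[2];
  params[0] = OSSL_PARAM_construct_utf8_string(param_key,
                                               const_cast<char*>(param_val), 0);
  params[1] = OSSL_PARAM_construct_end();
  RawVector out(outsz);
  size_t got = 0;
  int ok = EVP_MAC_init(ctx, RAW(key), key.size(), params) &&
           EVP_MAC_update(ctx, RAW(msg), msg.size()) &&
           EVP_MAC_final(ctx, RAW(out), &got, outsz);
  EVP_MAC_CTX_free(ctx);
  EVP_MAC_free(mac);
  if (!ok || got != outsz) stop("MAC computation failed");
  return out;
}

// [[Rcpp::export]]
RawVector cx_cmac_aes128(RawVector key, RawVector msg) {
  if (key.size() != 16) stop("CMAC-AES128 key must be 16 bytes");
  return mac_oneshot("CMAC", OSSL_MAC_PARAM_CIPHER, "AES-128-CBC", key, msg, 16);
}

// [[Rcpp::export]]
RawVector cx_hmac_sha512(RawVector key, RawVector msg) {
  return mac_oneshot("HMAC", OSSL_MAC_PARAM_DIGEST, "SHA-512", key, msg, 64);
}

// [[Rcpp::export]]
RawVector cx_gcm_seal(RawVector key, RawVector iv, RawVector pt) {
  if (key.size() != 16) stop("AES-128 key must be 16 bytes");
  if (iv.size() != 12) stop("GCM nonce must be 12 bytes");
  EVP_CIPHER_CTX* ctx = EVP_CIPHER_CTX_new();
  if (!ctx) stop("cipher context allocation failed");
  RawVector out(pt.size() + 16);
  int len = 0, total = 0, ok = 1;
  ok = ok && EVP_EncryptInit_ex(ctx, EVP_aes_128_gcm(), nullptr, RAW(key), RAW(iv));
  if (pt.size() > 0) {
    ok = ok && EVP_EncryptUpdate(ctx, RAW(out), &len, RAW(pt), pt.size());
    total = len;
  }
  ok = ok && EVP_EncryptFinal_ex(ctx, RAW(out) + total, &len);
  ok = ok && EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_GET_TAG, 16,
                                 RAW(out) + pt.size());
  EVP_CIPHER_CTX_free(ctx);
  if (!ok) stop("GCM encryption failed");
  return out;
}

// Returns plaintext, or R NULL when authentication fails.
// [[Rcpp::export]]
SEXP cx_gcm_open(RawVector key, RawVector iv, RawVector ct) {
  if (key.size() != 16) stop("AES-128 key must be 16 bytes");
  if (iv.size() != 12) stop("GCM nonce must be 12 bytes");
  if (ct.size() < 16) stop("ciphertext shorter than the GCM tag");
  size_t body = ct.size() - 16;
  EVP_CIPHER_CTX* ctx = EVP_CIPHER_CTX_new();
  if (!ctx) stop("cipher context allocation failed");
  RawVector out(body);
  int len = 0, ok = 1;
  ok = ok && EVP_DecryptInit_ex(ctx, EVP_aes_128_gcm(), nullptr, RAW(key), RAW(iv));
  if (body > 0) ok = ok && EVP_DecryptUpdate(ctx, RAW(out), &len, RAW(ct), body);
  std::vector<unsigned char> tag(RAW(ct) + body, RAW(ct) + ct.size());
  ok = ok && EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_SET_TAG, 16, tag.data());
  int fin = ok ? EVP_DecryptFinal_ex(ctx, RAW(out) + len, &len) : 0;
  EVP_CIPHER_CTX_free(ctx);
  if (!ok) stop("GCM decryption failed");
  if (fin != 1) return R_NilValue;
  return out;
}
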