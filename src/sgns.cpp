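// Skip-gram with negative sampling, single-threaded and deterministic.
// Uses its own splitmix64/xoshiro-style RNG so results depend only on the
// seed argument, never on R's RNG state.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
    uint64_t s;
    explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
    uint64_t next() {
        // splitmix64
        uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
    if (x > 8.0) return 1.0;
    if (x < -8.0) return 0.0;
    return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = "sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab, int dim, int window,
                         int negative, int epochs, double alpha,
                         NumericVector counts, int seed) {
    const int table_size = 100000;
    std::vector<int> unigram(table_size);
    // negative-sampling table: unigram distribution to the 3/4 power
    {
        double total = 0.0;
        for (int i = 0; i < vocab; ++i) total += std::pow(counts[i], 0.75);
        double cum = std::pow(counts[0], 0.75) / total;
        int w = 0;
        for (int i = 0; i < table_size; ++i) {
            unigram[i] = w;
            if ((i + 1.0) / table_size > cum && w < vocab - 1) {
                ++w;
                cum += std::pow(counts[w], 0.75) / total;
            }
        }
    }

    Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
    std::vector<double> in((size_t)vocab * dim), out((size_t)vocab * dim, 0.0);
    for (size_t i = 0; i < in.size(); ++i)
        in[i] = (rng.unif() - 0.5) / dim;

    // total centre positions, for linear learning-rate decay
    long long total_pos = 0;
    for (int s = 0; s < sentences.size(); ++s)
        total_pos += ((IntegerVector)sentences[s]).size();
    total_pos *= epochs;
    const double min_alpha = alpha / 10000.0;

    std::vector<double> grad(dim);
    long long done = 0;
    for (int ep = 0; ep < epochs; ++ep) {
        for (int s = 0; s < sentences.size(); ++s) {
            IntegerVector sent = sentences[s];
            const int n = sent.size();
            for (int pos = 0; pos < n; ++pos, ++done) {
                double lr = alpha * (1.0 - (double)done / (double)total_pos);
                if (lr < min_alpha) lr = min_alpha;
                const int centre = sent[pos];
                const int b = 1 + rng.below(window); // dynamic window
                for (int off = -b; off <= b; ++off) {
                    if (off == 0) continue;
                    const int cpos = pos + off;
                    if (cpos < 0 || cpos >= n) continue;
                    const int ctx = sent[cpos];
                    double* vi = &in[(size_t)centre * dim];
                    std::fill(grad.begin(), grad.end(), 0.0);
                    for (int k = 0; k <= negative; ++k) {
                        int target; double label;
                        if (k == 0) { target = ctx; label = 1.0; }
                        else {
                            target = unigram[rng.below(table_size)];
                            if (target == ctx) continue;
                            label = 0.0;
                        }
                        double* vo = &out[(size_t)target * dim];
                        double dot = 0.0;
                        for (int j = 0; j < dim; ++j) dot += vi[j] * vo[j];
                        const double g = (label - sigmoid(dot)) * lr;
                        for (int j = 0; j < dim; ++j) {
                            grad[j] += g * vo[j];
                            vo[j] += g * vi[j];
                        }
                    }
                    for (int j = 0; j < dim; ++j) vi[j] += grad[j];
                }
            }
        }
    }

    NumericMatrix res(vocab, dim);
    for (int i = 0; i < vocab; ++i)
        for (int j = 0; j < dim; ++j)
            res(i, j) = in[(size_t)i * dim + j];
    return res;
}
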