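#ifndef DANTE_NET_H
#define DANTE_NET_H

#include <RcppArmadillo.h>
#include <random>

struct AdamState {
  arma::fmat mW, vW;
  arma::fvec mb, vb;
};

struct ConvLayer {
  arma::fmat W;  // Cout x (Cin*k)
  arma::fvec b;
  AdamState ad;
};

struct BNLayer {
  arma::fvec gamma, beta, rmean, rvar;
  AdamState ad;
  arma::fmat mg, vg;
  arma::fvec mgam, vgam, mbet, vbet;
};

struct DenseLayer {
  arma::fmat W;
  arma::fvec b;
  AdamState ad;
};

struct Net {
  int d = 0, n_blocks = 6, dense_width = 32;
  std::vector<int> ks;          // kernel size per block (odd)
  std::vector<int> chans;       // output channels per block
  std::vector<char> pool_flag;  // stride-2 average pooling after block?
  double dropout = 0.1;
  bool use_norm = true;
  std::vector<ConvLayer> convs;
  std::vector<BNLayer> bns;
  DenseLayer fc1, fc2;
  long adam_t = 0;
};

struct FwdCache;

// Evaluation-mode forward pass on a batch (rows of X are samples in [0,1]^d).
arma::vec net_predict(Net *net, const arma::mat &X);

#endif
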