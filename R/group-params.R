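# Pre-generated public group parameter sets (see ?group_params). The two
# builtin safe-prime groups were produced once with group_setup(bits, seed)
# at seeds 512001 and 2048001 and frozen here; a unit test re-verifies the
# primality and generator invariants. "toy" (q = 23, p = 11, g = 2) exists
# for worked examples and arithmetic tests only.

.builtin_groups <- list(
  `toy` = list(p = "b", q = "17", g = "2"),
  `builtin-512` = list(p = "5b070a6c4eb4a5857f598a4a3617c9d1132478573f75ee5c2bb95777ca9068c788c88d326eb0e0dcc4ab952b11fbf92e47b9b6cd9493f23293e002cecf287e23", q = "b60e14d89d694b0afeb314946c2f93a22648f0ae7eebdcb85772aeef9520d18f11911a64dd61c1b989572a5623f7f25c8f736d9b2927e46527c0059d9e50fc47",
                       g = "97c06edff1d597df18ed67beb9da8b7de6c8a0ef51d507dc40d882faad7396fa635ef6a7b3328bd5ca5897728a1422c4b280aeec0b8f078894a61691f47d6a77"),
  `builtin-2048` = list(p = "722b4120c23e15a6a7fdaa815dd4b17023348a010d2873f4869a5066239a2c79bac9eefad2342991cd6be953880d03ae4855fc889341f23c3b48b361407dc08af5ed28c3b7f191bc35ce3703825452429e2e8783bb37b66f2ff3dbe0f17769115602d32f6d493c2686385dbdfbed3afcf7089d02c4d4e07c9814bb25efd3862126e630f29f0f95d55e694ffee607eb2ec988ae4e9b13a0433351bc796f33a93564809fadeff37e559c536c05e92b3db0127629b3a29d07a4db9c88432b27d6de23fbe28804560531dc5792b6cc5fc3b905eafd92dcacbd2601c4498661bac4c968e7d736603ea830402e169bc7d13de4c3334c1cde9da95dd7df401cfa21b117", q = "e4568241847c2b4d4ffb5502bba962e0466914021a50e7e90d34a0cc473458f37593ddf5a46853239ad7d2a7101a075c90abf9112683e478769166c280fb8115ebda51876fe323786b9c6e0704a8a4853c5d0f07766f6cde5fe7b7c1e2eed222ac05a65eda92784d0c70bb7bf7da75f9ee113a0589a9c0f93029764bdfa70c424dcc61e53e1f2baabcd29ffdcc0fd65d93115c9d3627408666a378f2de67526ac9013f5bdfe6fcab38a6d80bd2567b6024ec5367453a0f49b7391086564fadbc47f7c51008ac0a63b8af256d98bf87720bd5fb25b9597a4c0388930cc3758992d1cfae6cc07d5060805c2d378fa27bc986669839bd3b52bbafbe8039f443622f",
                        g = "85c134853f7383b63fd1cde7c58caaf9e68a52a111d851acc4bf0d9832a2bfea46ad8a563b5b4361dce8e9e5551f73f892a0f4809be92356e5d5e8184337a100ba2fc3430a6eb546faa8ffe078d1395949ff7f62a556d2df9325da3a8ac4adede67fa097350ce4279d113f2dc365c2c70d1f341d2e710f89f5048be4c784c05c074ab593736672a033898ddf602310481a7cfb23473714c98afb4d7c756b6839c027ea185d2d47adf5601f5e487cd311da7240fc61d4de4535c64591d0de3d13a03f11e80ab71849a2263ee9613996f494dc6fe317d40d934762698331639caded5f14d7d81c39ed16d12d94e5b684f06a278398abbd7a3dc792f443c6912303")
)
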