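{"schema":"dopaphore/anchor_set/1","frame_tag":"synthetic-pocket-fixture","anchors":[{"name":"Ser193:OG","element":"O","role":"both","x":-4.70340767724505,"y":1.19573042178598,"z":-5.55111512312578e-16},{"name":"Ser193:O","element":"O","role":"acceptor","x":-3.50340767724505,"y":-0.804269578214023,"z":1.5},{"name":"His393:NE2","element":"N","role":"both","x":-3.90340767724505,"y":3.79573042178598,"z":1.4},{"name":"Asn186:OD1","element":"O","role":"both","x":-2.40340767724505,"y":5.99573042178598,"z":3.4},{"name":"Asp114:OD","element":"O","role":"acceptor","x":5.96741221833974,"y":0.999999999999999,"z":3.46755908469892}],"hydrogen_sites":[{"x":1.26263051197067,"y":0.117075476151712,"z":2.40582024796381,"tag":"aliphatic_H"},{"x":1.51737931010842,"y":4.19323518503653,"z":1.11087251251842,"tag":"polar_H"},{"x":2.89304422098816,"y":-3.68048745604979,"z":-2.41641358209431,"tag":"aromatic_H"},{"x":3.42700685941153,"y":-3.43733368289597,"z":2.66334640198025,"tag":"aliphatic_H"},{"x":1.30109991672283,"y":1.8058195232159,"z":-2.05154502838204,"tag":"aliphatic_H"},{"x":5.8399087650031,"y":3.30527400717205,"z":2.51301083909309,"tag":"aromatic_H"},{"x":-1.12012267702791,"y":2.33203961089188,"z":-1.90383371927806,"tag":"aromatic_H"},{"x":4.91662179246127,"y":-2.74550672761373,"z":4.94697931818371,"tag":"aliphatic_H"},{"x":4.43926108273178,"y":2.33621821925114,"z":5.93735670520311,"tag":"aliphatic_H"},{"x":0.504315898512955,"y":-4.81986121577242,"z":-1.17546765633037,"tag":"aliphatic_H"},{"x":-0.0300349567770392,"y":3.2711709275806,"z":1.69616628072194,"tag":"aromatic_H"},{"x":4.30773742177448,"y":-6.41035717185238,"z":0.954956256832861,"tag":"aromatic_H"},{"x":3.7522603176026,"y":-3.55301879530272,"z":-2.26457939328179,"tag":"aromatic_H"},{"x":7.88855730488359,"y":-1.75061848325835,"z":-2.57766465105995,"tag":"aliphatic_H"},{"x":2.24763121519065,"y":2.60892930577164,"z":3.24504901289541,"tag":"aliphatic_H"}],"ring_centroids":[{"x":0,"y":0,"z":4.8},{"x":0,"y":0,"z":-4.8}]}
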