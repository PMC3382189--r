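{"schema":"dopaphore/pharm_model/1","frame_tag":"reference-agonist-frame","features":[{"name":"AspTM3","kinds":["cation"],"center":[4.76741221833974,-8.88178419700125e-16,1.26755908469892],"radius":1,"essential":true},{"name":"Aro","kinds":["aromatic"],"center":[0,0,0],"radius":1,"essential":true,"direction":[0,0,1],"direction_tol":30},{"name":"SerTM5","kinds":["donor_proj","acceptor_proj"],"center":[-4.70340767724505,1.19573042178598,-5.55111512312578e-16],"radius":1,"essential":false}],"excluded_volumes":[{"center":[1.26263051197067,0.117075476151712,2.40582024796381],"radius":2,"origin_tag":"aliphatic_H"},{"center":[1.51737931010842,4.19323518503653,1.11087251251842],"radius":1.8,"origin_tag":"polar_H"},{"center":[2.89304422098816,-3.68048745604979,-2.41641358209431],"radius":1.8,"origin_tag":"aromatic_H"},{"center":[3.42700685941153,-3.43733368289597,2.66334640198025],"radius":2,"origin_tag":"aliphatic_H"},{"center":[1.30109991672283,1.8058195232159,-2.05154502838204],"radius":2,"origin_tag":"aliphatic_H"},{"center":[5.8399087650031,3.30527400717205,2.51301083909309],"radius":1.8,"origin_tag":"aromatic_H"},{"center":[-1.12012267702791,2.33203961089188,-1.90383371927806],"radius":1.8,"origin_tag":"aromatic_H"},{"center":[4.91662179246127,-2.74550672761373,4.94697931818371],"radius":2,"origin_tag":"aliphatic_H"},{"center":[4.43926108273178,2.33621821925114,5.93735670520311],"radius":2,"origin_tag":"aliphatic_H"},{"center":[0.504315898512955,-4.81986121577242,-1.17546765633037],"radius":2,"origin_tag":"aliphatic_H"},{"center":[-0.0300349567770392,3.2711709275806,1.69616628072194],"radius":1.8,"origin_tag":"aromatic_H"},{"center":[4.30773742177448,-6.41035717185238,0.954956256832861],"radius":1.8,"origin_tag":"aromatic_H"},{"center":[3.7522603176026,-3.55301879530272,-2.26457939328179],"radius":1.8,"origin_tag":"aromatic_H"},{"center":[7.88855730488359,-1.75061848325835,-2.57766465105995],"radius":2,"origin_tag":"aliphatic_H"},{"center":[2.24763121519065,2.60892930577164,3.24504901289541],"radius":2,"origin_tag":"aliphatic_H"},{"center":[0,0,4.8],"radius":2.5,"origin_tag":"ring_centroid"},{"center":[0,0,-4.8],"radius":2.5,"origin_tag":"ring_centroid"}],"exclO":{"center":[1.8414050800804,2.00898595534499,0.361509880817921],"radius":1.5}}
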