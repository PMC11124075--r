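host,mode,phase,charge_method,elec,rep,disp,ff
alpha,BS,gas,MK,-9.4,8.4,-23.1,-24.1
alpha,BS,gas,CHELPG,-9.4,8.4,-23.1,-24.1
alpha,BS,gas,RESP,-9.6,8.4,-23.1,-24.2
alpha,BS,gas,RESP2,-10.8,8.4,-23.1,-25.5
alpha,BS,gas,FFMD,-9.9,8.4,-23.1,-24.5
alpha,BP,gas,MK,-3.4,16.3,-32.7,-19.8
alpha,BP,gas,CHELPG,-3.0,16.3,-32.7,-19.3
alpha,BP,gas,RESP,-3.7,16.3,-32.7,-20.1
alpha,BP,gas,RESP2,-4.4,16.3,-32.7,-20.8
alpha,BP,gas,FFMD,-2.8,16.3,-32.7,-19.2
beta,BS,gas,MK,-4.2,19.8,-41.7,-26.0
beta,BS,gas,CHELPG,-3.6,19.8,-41.7,-25.5
beta,BS,gas,RESP,-4.7,19.8,-41.7,-26.5
beta,BS,gas,RESP2,-6.0,19.8,-41.7,-27.8
beta,BS,gas,FFMD,-3.9,19.8,-41.7,-25.7
beta,BP,gas,MK,-10.7,10.6,-27.1,-27.3
beta,BP,gas,CHELPG,-10.5,10.6,-27.1,-27.0
beta,BP,gas,RESP,-10.4,10.6,-27.1,-26.9
beta,BP,gas,RESP2,-12.9,10.6,-27.1,-29.4
beta,BP,gas,FFMD,-11.4,10.6,-27.1,-27.9
gamma,BS,gas,MK,-4.5,9.1,-27.8,-23.2
gamma,BS,gas,CHELPG,-4.1,9.1,-27.8,-22.8
gamma,BS,gas,RESP,-4.0,9.1,-27.8,-22.7
gamma,BS,gas,RESP2,-5.5,9.1,-27.8,-24.2
gamma,BS,gas,FFMD,-6.2,9.1,-27.8,-24.9
gamma,BP,gas,MK,-4.3,6.3,-23.8,-21.8
gamma,BP,gas,CHELPG,-4.1,6.3,-23.8,-21.6
gamma,BP,gas,RESP,-4.2,6.3,-23.8,-21.7
gamma,BP,gas,RESP2,-5.5,6.3,-23.8,-22.9
gamma,BP,gas,FFMD,-5.3,6.3,-23.8,-22.7
alpha,BS,water,MK,-8.3,6.6,-20.0,-21.7
alpha,BS,water,CHELPG,-8.4,6.6,-20.0,-21.8
alpha,BS,water,RESP,-8.5,6.6,-20.0,-21.9
alpha,BS,water,RESP2,-9.5,6.6,-20.0,-22.9
alpha,BS,water,FFMD,-8.4,6.6,-20.0,-21.8
alpha,BP,water,MK,-3.0,14.4,-31.6,-20.2
alpha,BP,water,CHELPG,-2.5,14.4,-31.6,-19.8
alpha,BP,water,RESP,-3.0,14.4,-31.6,-20.2
alpha,BP,water,RESP2,-3.6,14.4,-31.6,-20.8
alpha,BP,water,FFMD,-1.8,14.4,-31.6,-19.1
beta,BS,water,MK,-3.3,17.8,-40.0,-25.5
beta,BS,water,CHELPG,-2.8,17.8,-40.0,-25.1
beta,BS,water,RESP,-4.0,17.8,-40.0,-26.2
beta,BS,water,RESP2,-5.1,17.8,-40.0,-27.4
beta,BS,water,FFMD,-2.9,17.8,-40.0,-25.2
beta,BP,water,MK,-10.6,9.8,-26.4,-27.1
beta,BP,water,CHELPG,-10.4,9.8,-26.4,-26.9
beta,BP,water,RESP,-10.2,9.8,-26.4,-26.8
beta,BP,water,RESP2,-12.6,9.8,-26.4,-29.2
beta,BP,water,FFMD,-11.3,9.8,-26.4,-27.9
gamma,BS,water,MK,-3.2,9.8,-26.4,-21.6
gamma,BS,water,CHELPG,-3.0,9.8,-26.4,-21.4
gamma,BS,water,RESP,-3.3,9.8,-26.4,-21.7
gamma,BS,water,RESP2,-4.6,9.8,-26.4,-23.0
gamma,BS,water,FFMD,-3.8,9.8,-26.4,-22.2
gamma,BP,water,MK,-3.5,7.1,-25.4,-20.9
gamma,BP,water,CHELPG,-3.4,7.1,-25.4,-20.7
gamma,BP,water,RESP,-3.3,7.1,-25.4,-20.7
gamma,BP,water,RESP2,-4.5,7.1,-25.4,-21.8
gamma,BP,water,FFMD,-4.3,7.1,-25.4,-21.7
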